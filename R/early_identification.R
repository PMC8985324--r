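#' Interim state of the current dose
#'
#' Captures the toxicity tally at the dose the next cohort would be
#' assigned to: the DLT count, the number of patients who completed the
#' assessment window DLT-free, and the follow-up fractions of pending
#' patients (enrolled, DLT-free so far, window not yet complete).
#'
#' @param n_dlt Number of DLTs observed at the dose.
#' @param n_nodlt Number of patients with a completed, DLT-free assessment.
#' @param pending Numeric vector of follow-up fractions in `[0, 1)`, one
#'   per pending patient (see [pending_fraction()]).
#' @return A list of class `"dose_state"` with elements `n`, `n_dlt`,
#'   `n_nodlt`, `pending`.
#' @examples
#' dose_state(n_dlt = 3, n_nodlt = 4, pending = c(2/3, 1/3))
#' @export
dose_state <- function(n_dlt, n_nodlt, pending = numeric()) {
  stopifnot(n_dlt >= 0, n_nodlt >= 0,
            n_dlt == floor(n_dlt), n_nodlt == floor(n_nodlt))
  if (any(pending < 0 | pending >= 1)) {
    stop("Pending follow-up fractions must lie in [0, 1); a fully followed ",
         "patient belongs in `n_nodlt`.", call. = FALSE)
  }
  structure(
    list(n = as.integer(n_dlt + n_nodlt + length(pending)),
         n_dlt = as.integer(n_dlt), n_nodlt = as.integer(n_nodlt),
         pending = as.numeric(pending)),
    class = "dose_state"
  )
}

#' @export
print.dose_state <- function(x, ...) {
  cat(sprintf("<dose_state> n = %d: %d DLT, %d completed DLT-free, %d pending",
              x$n, x$n_dlt, x$n_nodlt, length(x$pending)))
  if (length(x$pending)) {
    cat(" (fractions ", paste(signif(x$pending, 3), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Follow-up fraction of a pending patient
#'
#' @param t_obs DLT-free follow-up observed so far (same units as
#'   `t_window`).
#' @param t_window Length of the DLT assessment window.
#' @return `t_obs / t_window`.
#' @examples
#' pending_fraction(35, 70)  # half the 70-day window
#' @export
pending_fraction <- function(t_obs, t_window) {
  stopifnot(t_window > 0)
  if (any(t_obs < 0) || any(t_obs > t_window)) {
    stop("Need 0 <= t_obs <= t_window; a patient past the window should be ",
         "recorded as completed.", call. = FALSE)
  }
  t_obs / t_window
}

#' Effective counts from an interim dose state
#'
#' Pending patients contribute their follow-up fraction as partial
#' non-toxicity evidence: `n_pend` is the summed fraction and the effective
#' DLT-free count is `n_e = n_nodlt + n_pend`.
#'
#' @param state A [dose_state()].
#' @return One-row tibble with columns `n_pend` and `n_e`.
#' @examples
#' effective_counts(dose_state(3, 4, c(2/3, 1/3)))  # n_pend = 1, n_e = 5
#' @export
effective_counts <- function(state) {
  stopifnot(inherits(state, "dose_state"))
  n_pend <- sum(state$pending)
  tibble::tibble(n_pend = n_pend, n_e = state$n_nodlt + n_pend)
}

#' Effective number of future patients for the retainment probability
#'
#' The dose-retainment probability treats the `r` patients not yet
#' enrolled, plus the unresolved portion of the pending patients, as the
#' future "trials" of a beta-binomial experiment.  Under the default
#' `"remaining_fraction"` convention each pending patient contributes the
#' fraction of the window still to run, `1 - f`, so a patient at the end
#' of the window adds nothing more; the `"literal"` convention adds the
#' elapsed fraction `f` instead.  The two coincide whenever the pending
#' fractions sum to the same value either way (as in every printed
#' worked example).
#'
#' @param r Number of remaining (not yet enrolled) patients.
#' @param state A [dose_state()].
#' @param convention `"remaining_fraction"` (default) or `"literal"`.
#' @return A single non-negative number.
#' @examples
#' future_trials(6, dose_state(3, 4, c(2/3, 1/3)))  # 7
#' @export
future_trials <- function(r, state,
                          convention = c("remaining_fraction", "literal")) {
  stopifnot(inherits(state, "dose_state"), length(r) == 1, r >= 0,
            r == floor(r))
  convention <- match.arg(convention)
  if (convention == "remaining_fraction") {
    r + sum(1 - state$pending)
  } else {
    r + sum(state$pending)
  }
}

#' Early-identification configuration
#'
#' @param threshold Retainment-probability threshold for stopping at an
#'   interior dose; default 0.4.
#' @param boundary_multiplier Factor applied to `threshold` at the minimum
#'   or maximum dose, where only one of the two decision directions
#'   exists; default 2 (so 0.8 with the default threshold).
#' @param zero_correction Amount added to both beta shape parameters when
#'   the DLT count (or, symmetrically, the effective DLT-free count) is
#'   zero, keeping the shapes positive; default 0.5.
#' @param rpend_convention Passed to [future_trials()].
#' @return A list of class `"ei_config"`.
#' @export
ei_config <- function(threshold = 0.4, boundary_multiplier = 2,
                      zero_correction = 0.5,
                      rpend_convention = c("remaining_fraction", "literal")) {
  stopifnot(threshold > 0, boundary_multiplier > 0, zero_correction > 0)
  if (threshold * boundary_multiplier > 1) {
    warning("threshold * boundary_multiplier exceeds 1: early identification ",
            "can never trigger at the minimum or maximum dose.", call. = FALSE)
  }
  structure(list(threshold = threshold,
                 boundary_multiplier = boundary_multiplier,
                 zero_correction = zero_correction,
                 rpend_convention = match.arg(rpend_convention)),
            class = "ei_config")
}

#' Dose-retainment probability at an interim look
#'
#' Predictive probability that, once the `r` remaining patients have been
#' treated at the current dose, the design's pre-tabulated decision at
#' `n + r` patients would still be "retain".  Future DLT counts follow a
#' generalized beta-binomial with shapes `(n_dlt, n_e)` — the observed DLT
#' count and effective DLT-free count — over `r_pend` effective future
#' trials (see [future_trials()]).  Writing `E` and `D` for the escalation
#' and de-escalation boundaries at `n + r`,
#' \deqn{P(\mathrm{retain}) = BB(D - 1 - n_{DLT};\, r_{pend}, n_{DLT}, n_e)
#'   - BB(E - n_{DLT};\, r_{pend}, n_{DLT}, n_e),}
#' the first term being the probability of not de-escalating and the
#' second of escalating.  When `n_dlt = 0` (or `n_e = 0`) both shapes get
#' the configured zero correction so the beta prior stays proper.  A
#' sentinel (`NA`) de-escalation boundary gives a not-de-escalate
#' probability of 1; a sentinel escalation boundary gives an escalation
#' probability of 0.
#'
#' @param state A [dose_state()] for the current dose.
#' @param r Number of remaining patients (planned `N` minus treated).
#' @param table An `ei_boundary_table` covering row `n + r`.
#' @param config An [ei_config()].
#' @return One-row tibble of class `"ei_retainment"` with columns
#'   `p_not_deescalate`, `p_escalate`, `p_retain`, `n_e`, `r_pend`,
#'   `boundary_e`, `boundary_d`.
#' @examples
#' tab <- boundary_table(design_spec("BOIN", 0.3), 18)
#' st <- dose_state(3, 4, c(2/3, 1/3))
#' retainment_probability(st, r = 6, tab)  # 0.500 - 0.096 = 0.404
#' @export
retainment_probability <- function(state, r, table, config = ei_config()) {
  stopifnot(inherits(state, "dose_state"), inherits(config, "ei_config"))
  row <- boundary_row(table, state$n + r)
  core <- retainment_core(state$n_dlt, state$n_nodlt, state$pending,
                          r, row$E, row$D, config)
  out <- tibble::tibble(
    p_not_deescalate = core$p_not_deescalate,
    p_escalate = core$p_escalate,
    p_retain = core$p_retain,
    n_e = core$n_e,
    r_pend = core$r_pend,
    boundary_e = row$E,
    boundary_d = row$D
  )
  class(out) <- c("ei_retainment", class(out))
  out
}

# allocation-free core shared with the trial engine
retainment_core <- function(n_dlt, n_nodlt, pending, r, E, D, config) {
  n_e <- n_nodlt + sum(pending)
  r_pend <- if (config$rpend_convention == "remaining_fraction") {
    r + sum(1 - pending)
  } else {
    r + sum(pending)
  }
  shape1 <- n_dlt
  shape2 <- n_e
  if (n_dlt == 0 || n_e == 0) {
    shape1 <- shape1 + config$zero_correction
    shape2 <- shape2 + config$zero_correction
  }
  p_nde <- if (is.na(D)) 1 else pbbinom(D - 1 - n_dlt, r_pend, shape1, shape2)
  p_esc <- if (is.na(E)) 0 else pbbinom(E - n_dlt, r_pend, shape1, shape2)
  list(p_not_deescalate = p_nde, p_escalate = p_esc,
       p_retain = p_nde - p_esc, n_e = n_e, r_pend = r_pend)
}

# verdict logic on core values, shared with the trial engine
ei_stat_threshold <- function(core, dose_position, config) {
  if (dose_position == "interior") {
    list(stat = core$p_retain, thr = config$threshold)
  } else if (dose_position == "maximum") {
    list(stat = core$p_not_deescalate,
         thr = config$threshold * config$boundary_multiplier)
  } else {
    list(stat = 1 - core$p_escalate,
         thr = config$threshold * config$boundary_multiplier)
  }
}

#' Early-identification decision
#'
#' Decides whether the MTD-estimation phase can stop now and declare the
#' current dose the MTD.  At an interior dose the trial stops when the
#' retainment probability exceeds the threshold.  At the maximum dose
#' escalation does not exist, so the criterion is the not-de-escalate
#' probability against the doubled threshold; at the minimum dose
#' de-escalation does not exist and the criterion is one minus the
#' escalation probability against the doubled threshold.
#'
#' @param result An `"ei_retainment"` row from [retainment_probability()].
#' @param dose_position `"interior"`, `"minimum"`, or `"maximum"`.
#' @param config An [ei_config()].
#' @return One-row tibble with columns `verdict` (`"stop"` or
#'   `"continue"`), `statistic`, and `threshold`.
#' @examples
#' tab <- boundary_table(design_spec("BOIN", 0.3), 18)
#' res <- retainment_probability(dose_state(3, 4, c(2/3, 1/3)), 6, tab)
#' ei_decision(res, "interior")  # stop: 0.404 > 0.4
#' @export
ei_decision <- function(result, dose_position = c("interior", "minimum",
                                                  "maximum"),
                        config = ei_config()) {
  dose_position <- match.arg(dose_position)
  stopifnot(inherits(result, "ei_retainment"))
  st <- ei_stat_threshold(result, dose_position, config)
  tibble::tibble(
    verdict = if (st$stat > st$thr) "stop" else "continue",
    statistic = st$stat,
    threshold = st$thr,
    dose_position = dose_position
  )
}
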
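#' Configure a dose-finding trial
#'
#' Collects everything needed to conduct one simulated phase I trial:
#' the design rule, planned sample size and cohort structure, accrual and
#' assessment timing, the optional early-identification rule, and the
#' safety rules (dose elimination, accrual suspension, no dose skipping is
#' always enforced).
#'
#' @param design An [design_spec()] object.
#' @param n_doses Number of dose levels.
#' @param n Planned sample size.
#' @param cohort_size Patients per cohort (default 3).
#' @param window DLT assessment window, in months.
#' @param accrual_rate Enrollment rate, patients per month.
#' @param accrual `"deterministic"` (fixed inter-arrival `1/accrual_rate`)
#'   or `"poisson"`.
#' @param tite If `TRUE` (default) conduct the time-to-event variant:
#'   decisions use pending patients' fractional follow-up.  If `FALSE`,
#'   each dose-assignment decision waits until every patient at the
#'   current dose has a resolved outcome (the plain model-assisted
#'   design).
#' @param ei An [ei_config()] to enable early identification of the MTD,
#'   or `NULL` (default) to disable it.  Only meaningful with
#'   `tite = TRUE`.
#' @param elimination_cutoff Posterior probability of excessive toxicity
#'   above which a dose (and all higher doses) is eliminated; default
#'   0.95.
#' @param elimination_min_n Minimum patients at a dose before elimination
#'   applies; default 3.
#' @param suspension_min_complete_fraction Minimum fraction of
#'   resolved outcomes at the current dose required before the next cohort
#'   may enroll under the TITE conduct; default 0.5.
#' @param start_dose Starting dose level (default 1, the lowest).
#' @return A list of class `"trial_config"`.
#' @export
trial_config <- function(design, n_doses = 6L, n = 36L, cohort_size = 3L,
                         window = 3, accrual_rate = 2,
                         accrual = c("deterministic", "poisson"),
                         tite = TRUE, ei = NULL,
                         elimination_cutoff = 0.95, elimination_min_n = 3L,
                         suspension_min_complete_fraction = 0.5,
                         start_dose = 1L) {
  stopifnot(inherits(design, "ei_design"), n_doses >= 1, n >= 1,
            cohort_size >= 1, window > 0, accrual_rate > 0,
            start_dose >= 1, start_dose <= n_doses)
  if (!is.null(ei)) stopifnot(inherits(ei, "ei_config"))
  cfg <- list(design = design, n_doses = as.integer(n_doses),
              n = as.integer(n), cohort_size = as.integer(cohort_size),
              window = window, accrual_rate = accrual_rate,
              accrual = match.arg(accrual), tite = tite, ei = ei,
              elimination_cutoff = elimination_cutoff,
              elimination_min_n = as.integer(elimination_min_n),
              suspension_min_complete_fraction =
                suspension_min_complete_fraction,
              start_dose = as.integer(start_dose))
  if (!is.null(ei)) cfg$table <- boundary_table(design, n_max = cfg$n)
  structure(cfg, class = "trial_config")
}

#' Accrual suspension check
#'
#' Under the TITE conduct a new cohort may only enroll while enough of the
#' current dose's outcomes have resolved (DLT observed or window
#' completed); otherwise accrual is suspended until the condition holds.
#'
#' @param n_resolved,n_treated Resolved and total patient counts at the
#'   current dose.
#' @param min_fraction Required resolved fraction.
#' @return `"enroll"` or `"suspend"`.
#' @export
suspension_check <- function(n_resolved, n_treated, min_fraction = 0.5) {
  stopifnot(n_treated >= 1, n_resolved >= 0, n_resolved <= n_treated)
  if (n_resolved / n_treated < min_fraction) "suspend" else "enroll"
}

#' Dose elimination check
#'
#' A dose is eliminated (together with all higher doses) when, with at
#' least `min_n` patients treated there, the posterior probability that
#' its DLT rate exceeds the target is above `cutoff`, under a
#' `Beta(1 + n_dlt, 1 + n_free)` posterior.  `n_free` may be fractional
#' under the TITE conduct.
#'
#' @param n_dlt DLT count at the dose.
#' @param n_free Effective DLT-free count.
#' @param n_treated Patients treated at the dose.
#' @param target Target DLT rate.
#' @param cutoff Posterior probability cutoff (default 0.95).
#' @param min_n Minimum patients before the rule applies (default 3).
#' @return `"keep"` or `"eliminate"`.
#' @examples
#' elimination_check(3, 0, 3, target = 0.3)  # P(p > 0.3) = 0.992: eliminate
#' @export
elimination_check <- function(n_dlt, n_free, n_treated, target,
                              cutoff = 0.95, min_n = 3L) {
  if (n_treated < min_n) return("keep")
  p_over <- stats::pbeta(target, 1 + n_dlt, 1 + n_free, lower.tail = FALSE)
  if (p_over > cutoff) "eliminate" else "keep"
}

#' Next dose under the no-skipping rule
#'
#' Moves at most one level per decision, never onto an eliminated dose:
#' a blocked escalation (top dose, or next level eliminated) retains, and
#' a blocked de-escalation (lowest dose) retains.
#'
#' @param current Current dose index.
#' @param action `"escalate"`, `"retain"`, or `"deescalate"`.
#' @param eliminated Logical vector of length `n_doses`.
#' @param n_doses Number of dose levels.
#' @return The next dose index.
#' @export
next_dose <- function(current, action, eliminated, n_doses) {
  stopifnot(current >= 1, current <= n_doses, !eliminated[current])
  if (action == "escalate") {
    if (current < n_doses && !eliminated[current + 1L]) current + 1L
    else current
  } else if (action == "deescalate") {
    if (current > 1L) current - 1L else current
  } else {
    current
  }
}

# weighted pool-adjacent-violators: isotonic (non-decreasing) fit of y
# with weights w
pava <- function(y, w) {
  n <- length(y)
  if (n <= 1) return(y)
  val <- y
  wt <- w
  len <- rep(1L, n)
  m <- n
  i <- 1L
  while (i < m) {
    if (val[i] > val[i + 1L] + 1e-12) {
      val[i] <- (val[i] * wt[i] + val[i + 1L] * wt[i + 1L]) /
        (wt[i] + wt[i + 1L])
      wt[i] <- wt[i] + wt[i + 1L]
      len[i] <- len[i] + len[i + 1L]
      val <- val[-(i + 1L)]; wt <- wt[-(i + 1L)]; len <- len[-(i + 1L)]
      m <- m - 1L
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  rep(val, len)
}

#' Select the MTD from final trial data
#'
#' Isotonic-regression based MTD selection: per-dose posterior mean DLT
#' rates under a vague `Beta(0.05, 0.05)` prior are made monotone by
#' weighted pool-adjacent-violators (weights = patients treated), and the
#' tried, non-eliminated dose whose isotonic estimate is closest to the
#' target is selected.  Ties go to the higher dose when the tied estimate
#' is below the target and to the lower dose when above.
#'
#' @param n_treated,n_dlt Integer vectors, one entry per dose level.
#' @param target Target DLT rate.
#' @param eliminated Logical vector (default none).
#' @return Selected dose index, or `NA_integer_` if no dose was tried or
#'   all tried doses are eliminated.
#' @examples
#' select_mtd(c(3, 6, 6), c(0, 1, 3), target = 0.3)  # dose 2
#' @export
select_mtd <- function(n_treated, n_dlt, target,
                       eliminated = rep(FALSE, length(n_treated))) {
  stopifnot(length(n_treated) == length(n_dlt),
            length(eliminated) == length(n_treated))
  cand <- which(n_treated > 0 & !eliminated)
  if (!length(cand)) return(NA_integer_)
  est <- (0.05 + n_dlt[cand]) / (0.1 + n_treated[cand])
  iso <- pava(est, n_treated[cand])
  dist <- abs(iso - target)
  tied <- which(dist <= min(dist) + 1e-12)
  pick <- if (iso[tied[1]] < target) max(tied) else min(tied)
  # mixed-sign ties: prefer the higher under-target dose
  under <- tied[iso[tied] < target]
  if (length(under) && length(under) < length(tied)) pick <- max(under)
  cand[pick]
}

#' Simulate one dose-finding trial
#'
#' Discrete-event conduct of a single trial under the configured design.
#' Patients arrive per the accrual model and enroll in cohorts at the
#' current dose.  At each cohort boundary the engine (in order) waits out
#' any accrual suspension, applies the dose-elimination rule, evaluates
#' the early-identification rule when enabled (with `r` = planned minus
#' treated), and otherwise applies the design's dose-assignment rule
#' under the no-skipping constraint.  A pending DLT-free patient
#' contributes the fraction of the window elapsed at the decision time; a
#' patient whose DLT has already onset contributes a full DLT.  On an EI
#' stop the study duration is the decision time itself (pending patients'
#' remaining follow-up is saved); otherwise the trial runs to `N` and the
#' duration is the last enrollment time plus the window, with the MTD
#' chosen by [select_mtd()].
#'
#' @param cfg A [trial_config()].
#' @param scenario An [scenario()] (or bare numeric vector of true DLT
#'   probabilities, one per dose).
#' @param seed Optional integer seed; ignored when `latent` is given.
#' @param latent Optional pre-drawn patient stream from
#'   [paired_latent_patients()], used to couple design variants.
#' @param keep_events If `FALSE`, skip building the event-log tibble
#'   (batch simulation drops it for speed).
#' @return A list of class `"ei_trial"`; see [tidy.ei_trial()] and
#'   [glance.ei_trial()] for tabular views.
#' @examples
#' cfg <- trial_config(design_spec("BOIN", 0.3), n_doses = 4, n = 12,
#'                     window = 3, accrual_rate = 2)
#' run_trial(cfg, scenario(c(0.05, 0.15, 0.3, 0.5)), seed = 1)
#' @export
run_trial <- function(cfg, scenario, seed = NULL, latent = NULL,
                      keep_events = TRUE) {
  stopifnot(inherits(cfg, "trial_config"))
  scenario <- as_scenario(scenario)
  if (length(scenario$p) != cfg$n_doses) {
    stop("Scenario supplies ", length(scenario$p), " dose probabilities but ",
         "the trial has ", cfg$n_doses, " dose levels.", call. = FALSE)
  }
  if (is.null(latent)) {
    if (!is.null(seed)) set.seed(seed)
    latent <- paired_latent_patients(scenario, cfg)
  }
  N <- cfg$n
  window <- cfg$window
  # per-patient records (filled as patients enroll)
  p_dose <- integer(N); p_enroll <- numeric(N)
  p_dlt <- logical(N); p_res <- numeric(N)  # resolution time (DLT or window)
  eliminated <- rep(FALSE, cfg$n_doses)
  current <- cfg$start_dose
  cohort_count <- 0L
  treated <- 0L
  stop_reason <- "completed"
  selected <- NA_integer_
  duration <- NA_real_
  ev_t <- numeric(0); ev_what <- character(0); ev_dose <- integer(0)
  log_ev <- function(t, what, dose) {
    ev_t[length(ev_t) + 1L] <<- t
    ev_what[length(ev_what) + 1L] <<- what
    ev_dose[length(ev_dose) + 1L] <<- dose
  }

  state_at <- function(dose, t) {
    idx <- which(p_dose[seq_len(treated)] == dose)
    n_dlt <- 0L; n_nodlt <- 0L; pending <- numeric(0)
    for (j in idx) {
      el <- t - p_enroll[j]
      if (p_dlt[j] && p_res[j] <= t) {
        n_dlt <- n_dlt + 1L
      } else if (el >= window) {
        if (p_dlt[j]) n_dlt <- n_dlt + 1L else n_nodlt <- n_nodlt + 1L
      } else {
        pending[length(pending) + 1L] <- el / window
      }
    }
    list(n = length(idx), n_dlt = n_dlt, n_nodlt = n_nodlt,
         pending = pmax(pending, 0))
  }

  for (i in seq_len(N)) {
    t <- latent$arrival[i]
    if (treated > 0) t <- max(t, p_enroll[treated])

    if (cohort_count == cfg$cohort_size) {
      # --- decision point before this patient can enroll ---
      idx <- which(p_dose[seq_len(treated)] == current)
      res_times <- p_res[idx]
      if (!cfg$tite) {
        t <- max(t, max(res_times))          # wait for complete data
      } else {
        need <- ceiling(cfg$suspension_min_complete_fraction * length(idx))
        if (need > 0) {
          t_need <- sort(res_times)[need]
          if (t_need > t) t <- t_need        # accrual suspension
        }
      }
      st <- state_at(current, t)
      eff <- st$n_nodlt + sum(st$pending)

      if (elimination_check(st$n_dlt, eff, st$n, cfg$design$target,
                            cfg$elimination_cutoff,
                            cfg$elimination_min_n) == "eliminate") {
        eliminated[current:cfg$n_doses] <- TRUE
        log_ev(t, "eliminate", current)
        if (current == 1L) {
          stop_reason <- "terminated"
          duration <- t
          break
        }
        current <- current - 1L
        cohort_count <- 0L
      } else {
        action <- dose_decision(st$n_dlt, eff, cfg$design)
        log_ev(t, action, current)
        prev <- current
        current <- next_dose(current, action, eliminated, cfg$n_doses)
        cohort_count <- 0L
        # a blocked de-escalation at the lowest dose is not dose
        # maintenance: the rule wants to leave, so no early declaration
        blocked_deesc <- action == "deescalate" && current == prev
        if (!is.null(cfg$ei) && !blocked_deesc) {
          # early identification concerns the dose the next cohort would
          # be assigned to, with that dose's own tallies
          st2 <- state_at(current, t)
          r <- N - treated
          row <- boundary_row(cfg$table, st2$n + r)
          core <- retainment_core(st2$n_dlt, st2$n_nodlt, st2$pending,
                                  r, row$E, row$D, cfg$ei)
          pos <- dose_position(current, cfg$n_doses, eliminated)
          sth <- ei_stat_threshold(core, pos, cfg$ei)
          if (sth$stat > sth$thr) {
            log_ev(t, "ei_stop", current)
            stop_reason <- "early_identification"
            selected <- current
            duration <- t
            break
          }
        }
      }
    }

    treated <- treated + 1L
    p_dose[treated] <- current
    p_enroll[treated] <- t
    p_dlt[treated] <- latent$u[i] < scenario$p[current]
    p_res[treated] <- t + if (p_dlt[treated]) {
      latent$onset[i] * window
    } else {
      window
    }
    log_ev(t, "enroll", current)
    cohort_count <- cohort_count + 1L
  }

  per_dose_n <- tabulate(p_dose[seq_len(treated)], cfg$n_doses)
  per_dose_dlt <- vapply(seq_len(cfg$n_doses), function(d) {
    sum(p_dlt[seq_len(treated)][p_dose[seq_len(treated)] == d])
  }, integer(1))

  if (stop_reason == "completed") {
    duration <- p_enroll[treated] + window
    selected <- select_mtd(per_dose_n, per_dose_dlt, cfg$design$target,
                           eliminated)
  }

  structure(list(
    selected_mtd = selected,
    stopped_early = stop_reason == "early_identification",
    stop_reason = stop_reason,
    n_treated = treated,
    duration = duration,
    dose_n = per_dose_n,
    dose_dlt = per_dose_dlt,
    eliminated = eliminated,
    events = if (keep_events) {
      tibble::tibble(time = ev_t, event = ev_what, dose = ev_dose)
    }
  ), class = "ei_trial")
}

dose_position <- function(current, n_doses, eliminated) {
  at_top <- current == n_doses ||
    (current < n_doses && eliminated[current + 1L])
  if (at_top) "maximum" else if (current == 1L) "minimum" else "interior"
}

#' @export
print.ei_trial <- function(x, ...) {
  cat("<ei_trial> ", x$stop_reason,
      "; MTD = ", ifelse(is.na(x$selected_mtd), "none", x$selected_mtd),
      "; n = ", x$n_treated,
      sprintf("; duration = %.2f months", x$duration), "\n", sep = "")
  invisible(x)
}
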
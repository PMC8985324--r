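#' Define a true-toxicity scenario
#'
#' A scenario fixes the true DLT probability of each dose level, the index
#' of the true MTD (the dose whose probability is closest to the target),
#' and the time-to-DLT model within the assessment window.  When even the
#' lowest dose is clearly over-toxic (`p[1] >= target + overdose_margin`)
#' no dose is the MTD and the correct trial outcome is to select none.
#'
#' @param p Numeric vector of true DLT probabilities, one per dose,
#'   non-decreasing.
#' @param target Target DLT rate used to locate the true MTD.
#' @param onset One of `"uniform"` (DLT onset uniform over the window,
#'   default) or `"weibull"`.
#' @param onset_shape,onset_scale Weibull parameters for the onset
#'   fraction of the window (used when `onset = "weibull"`; the draw is
#'   truncated to the window).  Shape > 1 with scale near 1 concentrates
#'   DLTs late in the window.
#' @param overdose_margin Margin above the target beyond which the lowest
#'   dose is considered to have no MTD; default 0.1.
#' @return A list of class `"ei_scenario"` with elements `p`, `true_mtd`,
#'   `onset`, `onset_shape`, `onset_scale`.
#' @examples
#' scenario(c(0.14, 0.30, 0.45, 0.55, 0.65, 0.75))  # true MTD = dose 2
#' @export
scenario <- function(p, target = 0.3, onset = c("uniform", "weibull"),
                     onset_shape = 2, onset_scale = 1,
                     overdose_margin = 0.1) {
  stopifnot(all(p >= 0), all(p <= 1))
  if (is.unsorted(p)) {
    stop("True DLT probabilities must be non-decreasing across doses.",
         call. = FALSE)
  }
  true_mtd <- if (p[1] >= target + overdose_margin) {
    NA_integer_
  } else {
    which.min(abs(p - target))
  }
  structure(list(p = as.numeric(p), true_mtd = true_mtd,
                 onset = match.arg(onset),
                 onset_shape = onset_shape, onset_scale = onset_scale),
            class = "ei_scenario")
}

as_scenario <- function(x, target = 0.3) {
  if (inherits(x, "ei_scenario")) x else scenario(x, target = target)
}

#' @export
print.ei_scenario <- function(x, ...) {
  cat("<ei_scenario> p = (", paste(signif(x$p, 3), collapse = ", "),
      "); true MTD = ",
      ifelse(is.na(x$true_mtd), "none", x$true_mtd),
      "; onset ", x$onset, "\n", sep = "")
  invisible(x)
}

#' Draw a random true-toxicity scenario
#'
#' The MTD position is uniform over the dose levels; its DLT probability
#' is drawn within `target` plus/minus 0.03, and the curve is extended
#' downward and upward with independent spacings drawn uniformly from
#' `[spacing_low, spacing_high]`, truncated to `[0.001, 0.95]`.
#'
#' @param target Target DLT rate.
#' @param n_doses Number of dose levels (at least 2).
#' @param spacing_low,spacing_high Bounds of the between-dose spacing.
#'   The defaults, 0.05 to 0.15, give closely spaced curves; 0.10 to 0.25
#'   gives well-separated ones.
#' @param ... Passed to [scenario()] (e.g. the onset model).
#' @return An `"ei_scenario"`.
#' @examples
#' set.seed(1)
#' random_scenario(0.3, 6)
#' @export
random_scenario <- function(target = 0.3, n_doses = 6L,
                            spacing_low = 0.05, spacing_high = 0.15, ...) {
  stopifnot(n_doses >= 2, spacing_low > 0, spacing_low <= spacing_high)
  mtd <- sample.int(n_doses, 1)
  p <- numeric(n_doses)
  p[mtd] <- stats::runif(1, target - 0.03, target + 0.03)
  if (mtd > 1) {
    for (d in (mtd - 1):1) {
      p[d] <- p[d + 1] - stats::runif(1, spacing_low, spacing_high)
    }
  }
  if (mtd < n_doses) {
    for (d in (mtd + 1):n_doses) {
      p[d] <- p[d - 1] + stats::runif(1, spacing_low, spacing_high)
    }
  }
  scenario(pmin(pmax(p, 0.001), 0.95), target = target, ...)
}

#' Latent patient stream shared across design variants
#'
#' Draws, for each prospective patient, the scheduled arrival offset, a
#' latent uniform `u` deciding DLT occurrence at any dose (`u < p[d]`,
#' monotonically coupled across doses), and the latent onset fraction of
#' the window at which a DLT would occur.  Running every design variant
#' on the same stream couples their sample paths, so paired comparisons
#' (percent change in duration or sample size) are differences on matched
#' trials rather than across independent Monte-Carlo noise.
#'
#' @param scenario An [scenario()].
#' @param cfg A [trial_config()] (supplies `n`, accrual model and rate).
#' @return A tibble with columns `arrival`, `u`, `onset`.
#' @export
paired_latent_patients <- function(scenario, cfg) {
  scenario <- as_scenario(scenario)
  N <- cfg$n
  arrival <- if (cfg$accrual == "deterministic") {
    (seq_len(N) - 1) / cfg$accrual_rate
  } else {
    c(0, cumsum(stats::rexp(N - 1, cfg$accrual_rate)))
  }
  onset <- if (scenario$onset == "uniform") {
    stats::runif(N)
  } else {
    cap <- stats::pweibull(1, scenario$onset_shape, scenario$onset_scale)
    stats::qweibull(stats::runif(N) * cap, scenario$onset_shape,
                    scenario$onset_scale)
  }
  tibble::tibble(arrival = pmax(arrival, 0), u = stats::runif(N),
                 onset = onset)
}

parse_design_label <- function(label, target = 0.3, ei = ei_config()) {
  x <- tolower(label)
  has_ei <- grepl("^ei-", x)
  x <- sub("^ei-", "", x)
  has_tite <- grepl("^tite-", x)
  x <- sub("^tite-", "", x)
  if (!x %in% c("mtpi", "keyboard", "boin")) {
    stop("Unknown design label: ", label,
         " (expected e.g. 'boin', 'tite-boin', 'ei-tite-boin').",
         call. = FALSE)
  }
  if (has_ei && !has_tite) {
    stop("Early identification requires the TITE conduct: use 'ei-tite-",
         x, "'.", call. = FALSE)
  }
  list(family = x, tite = has_tite, ei = if (has_ei) ei else NULL)
}

#' Run a batch simulation study
#'
#' Simulates `n_reps` trials per scenario for each requested design
#' variant and aggregates the operating characteristics the dose-finding
#' literature reports: the percentage of correct MTD selection (PCMS),
#' the percentage of trials stopped by early identification, and the
#' average study duration and sample size.  Design variants are named by
#' label: `"boin"` (plain model-assisted), `"tite-boin"` (time-to-event),
#' `"ei-tite-boin"` (time-to-event with early identification), and
#' likewise for `mtpi` and `keyboard`.  All variants of a replicate share
#' one latent patient stream ([paired_latent_patients()]), and per-design
#' percent changes in duration and sample size are reported against the
#' matching non-EI variants where present.
#'
#' @param scenarios A single [scenario()] or list of them.
#' @param designs Character vector of design labels.
#' @param n_reps Simulated trials per scenario and design.
#' @param base_seed Integer; every replicate's stream is derived from it.
#' @param target Target DLT rate.
#' @param ei An [ei_config()] applied to the `ei-` variants.
#' @param n_doses,n,cohort_size,window,accrual_rate,... Passed to
#'   [trial_config()].
#' @return A tibble of class `"ei_sim_summary"`, one row per design and
#'   scenario, with columns `design`, `scenario`, `n_reps`, `pcms`,
#'   `pct_early`, `avg_duration`, `avg_n`, `pct_change_duration`,
#'   `pct_change_n` (vs the `tite-` counterpart, `NA` where absent),
#'   `selection` (list-column: selection percentage per dose).  The
#'   per-trial results are attached as attribute `"trials"`.
#' @examples
#' sc <- scenario(c(0.14, 0.30, 0.45, 0.55))
#' run_simulation(sc, designs = c("tite-boin", "ei-tite-boin"),
#'                n_reps = 20, base_seed = 1, n_doses = 4, n = 18)
#' @export
run_simulation <- function(scenarios, designs = c("tite-boin", "ei-tite-boin"),
                           n_reps = 1000L, base_seed = 1L, target = 0.3,
                           ei = ei_config(), n_doses = 6L, n = 36L,
                           cohort_size = 3L, window = 3, accrual_rate = 2,
                           ...) {
  if (inherits(scenarios, "ei_scenario")) scenarios <- list(scenarios)
  scenarios <- lapply(scenarios, as_scenario, target = target)
  parsed <- lapply(designs, parse_design_label, target = target, ei = ei)
  cfgs <- lapply(parsed, function(p) {
    trial_config(design_spec(p$family, target = target),
                 n_doses = n_doses, n = n, cohort_size = cohort_size,
                 window = window, accrual_rate = accrual_rate,
                 tite = p$tite, ei = p$ei, ...)
  })
  names(cfgs) <- designs

  n_total <- length(scenarios) * n_reps * length(designs)
  col_design <- character(n_total); col_scen <- integer(n_total)
  col_rep <- integer(n_total); col_sel <- integer(n_total)
  col_correct <- logical(n_total); col_early <- logical(n_total)
  col_n <- integer(n_total); col_dur <- numeric(n_total)
  k <- 0L
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    for (rep in seq_len(n_reps)) {
      seed <- (as.numeric(base_seed) * 48271 + s * 100003 + rep) %% 2147483629
      set.seed(as.integer(seed))
      latent <- paired_latent_patients(sc, cfgs[[1]])
      for (d in seq_along(designs)) {
        tr <- run_trial(cfgs[[d]], sc, latent = latent, keep_events = FALSE)
        k <- k + 1L
        col_design[k] <- designs[d]; col_scen[k] <- s; col_rep[k] <- rep
        col_sel[k] <- tr$selected_mtd
        col_correct[k] <- identical(tr$selected_mtd, sc$true_mtd) ||
          (is.na(tr$selected_mtd) && is.na(sc$true_mtd))
        col_early[k] <- tr$stopped_early
        col_n[k] <- tr$n_treated; col_dur[k] <- tr$duration
      }
    }
  }
  trials <- tibble::tibble(design = col_design, scenario = col_scen,
                           rep = col_rep, selected = col_sel,
                           correct = col_correct, early = col_early,
                           n_treated = col_n, duration = col_dur)

  smry <- trials |>
    dplyr::group_by(.data$design, .data$scenario) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      pcms = 100 * mean(.data$correct),
      pct_early = 100 * mean(.data$early),
      avg_duration = mean(.data$duration),
      avg_n = mean(.data$n_treated),
      selection = list(100 * tabulate(.data$selected[!is.na(.data$selected)],
                                      n_doses) / dplyr::n()),
      .groups = "drop"
    )

  base_of <- function(lab) sub("^ei-", "", lab)
  smry <- smry |>
    dplyr::group_by(.data$scenario) |>
    dplyr::mutate(
      pct_change_duration = pct_change_col(.data$design, .data$avg_duration,
                                           base_of),
      pct_change_n = pct_change_col(.data$design, .data$avg_n, base_of)
    ) |>
    dplyr::ungroup()
  attr(smry, "trials") <- trials
  class(smry) <- c("ei_sim_summary", class(smry))
  smry
}

pct_change_col <- function(design, value, base_of) {
  out <- rep(NA_real_, length(design))
  for (i in seq_along(design)) {
    if (grepl("^ei-", design[i])) {
      j <- match(base_of(design[i]), design)
      if (!is.na(j)) out[i] <- 100 * (value[i] - value[j]) / value[j]
    }
  }
  out
}

#' Plot a simulation summary
#'
#' Bar charts of the four operating characteristics by design and
#' scenario.
#'
#' @param object An `"ei_sim_summary"` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ei_sim_summary <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("design", "scenario", "pcms", "pct_early",
                  "avg_duration", "avg_n") |>
    tidyr::pivot_longer(c("pcms", "pct_early", "avg_duration", "avg_n"),
                        names_to = "metric")
  long$metric <- factor(long$metric,
                        c("pcms", "pct_early", "avg_duration", "avg_n"),
                        c("PCMS (%)", "early identification (%)",
                          "mean duration (months)", "mean sample size"))
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$scenario), .data$value,
                                     fill = .data$design)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "scenario", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
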
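#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulated trial
#'
#' @param x An `"ei_trial"` from [run_trial()].
#' @param ... Unused.
#' @return `tidy()`: one row per dose level with columns `dose`, `n`,
#'   `n_dlt`, `rate`, `eliminated`, `selected`.  `glance()`: a one-row
#'   trial summary.
#' @export
tidy.ei_trial <- function(x, ...) {
  tibble::tibble(
    dose = seq_along(x$dose_n),
    n = x$dose_n,
    n_dlt = x$dose_dlt,
    rate = ifelse(x$dose_n > 0, x$dose_dlt / x$dose_n, NA_real_),
    eliminated = x$eliminated,
    selected = seq_along(x$dose_n) == (x$selected_mtd %||% NA_integer_) &
      !is.na(x$selected_mtd)
  )
}

#' @rdname tidy.ei_trial
#' @export
glance.ei_trial <- function(x, ...) {
  tibble::tibble(
    selected_mtd = x$selected_mtd,
    stopped_early = x$stopped_early,
    stop_reason = x$stop_reason,
    n_treated = x$n_treated,
    duration = x$duration
  )
}

#' Tidy a simulation summary
#'
#' @param x An `"ei_sim_summary"` from [run_simulation()].
#' @param ... Unused.
#' @return `tidy()`: the per-design, per-scenario metric rows (the
#'   summary itself, as a plain tibble, with the selection distribution
#'   unnested into `sel_dose_*` columns).  `glance()`: one row per design
#'   averaging over scenarios.
#' @export
tidy.ei_sim_summary <- function(x, ...) {
  out <- tibble::as_tibble(x)
  sel <- do.call(rbind, out$selection)
  colnames(sel) <- paste0("sel_dose_", seq_len(ncol(sel)))
  dplyr::bind_cols(dplyr::select(out, -"selection"),
                   tibble::as_tibble(sel))
}

#' @rdname tidy.ei_sim_summary
#' @export
glance.ei_sim_summary <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$design) |>
    dplyr::summarise(
      n_scenarios = dplyr::n(),
      pcms = mean(.data$pcms),
      pct_early = mean(.data$pct_early),
      avg_duration = mean(.data$avg_duration),
      avg_n = mean(.data$avg_n),
      .groups = "drop"
    )
}
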
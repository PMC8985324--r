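#' Build the escalation/de-escalation decision-boundary table
#'
#' Tabulates, for every number of patients `n = 1..n_max` treated at the
#' current dose, the largest DLT count that still escalates (`escalate_le`)
#' and the smallest DLT count that de-escalates (`deescalate_ge`) under the
#' design's decision rule.  A cell is `NA` when no DLT count produces that
#' action at that `n` (e.g. a single patient can never force de-escalation
#' under some rules).  These are the pre-tabulated boundaries a
#' model-assisted trial conducts itself with, and the early-identification
#' rule reads its `E` and `D` values from the row at `n + r`.
#'
#' @param design An [design_spec()] object.
#' @param n_max Largest sample size to tabulate (the trial's planned `N`,
#'   or more).
#' @return A tibble of class `"ei_boundary_table"` with columns `n`,
#'   `escalate_le`, `deescalate_ge`, carrying the design as an attribute.
#' @examples
#' boundary_table(design_spec("BOIN", 0.3), n_max = 18)
#' @export
boundary_table <- function(design, n_max = 36L) {
  stopifnot(inherits(design, "ei_design"), n_max >= 1)
  rows <- purrr::map(seq_len(n_max), function(n) {
    acts <- vapply(0:n, function(k) dose_decision(k, n - k, design),
                   character(1))
    esc <- which(acts == "escalate") - 1L
    des <- which(acts == "deescalate") - 1L
    tibble::tibble(
      n = as.integer(n),
      escalate_le = if (length(esc)) max(esc) else NA_integer_,
      deescalate_ge = if (length(des)) min(des) else NA_integer_
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- validate_boundary_table(out)
  attr(out, "design") <- design
  class(out) <- c("ei_boundary_table", class(out))
  out
}

validate_boundary_table <- function(tbl) {
  need <- c("n", "escalate_le", "deescalate_ge")
  if (!all(need %in% names(tbl))) {
    stop("Boundary table needs columns n, escalate_le, deescalate_ge.",
         call. = FALSE)
  }
  tbl <- dplyr::arrange(tbl, .data$n)
  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) {
      stop(sprintf("Boundary table invalid at row n = %d: %s", tbl$n[i[1]], msg),
           call. = FALSE)
    }
  }
  both <- !is.na(tbl$escalate_le) & !is.na(tbl$deescalate_ge)
  bad_row(both & tbl$escalate_le + 1L > tbl$deescalate_ge,
          "escalation boundary must lie below de-escalation boundary")
  bad_row(!is.na(tbl$deescalate_ge) & tbl$deescalate_ge > tbl$n,
          "de-escalation boundary exceeds n")
  mono <- function(x) {
    x <- x[!is.na(x)]
    length(x) < 2 || all(diff(x) >= 0)
  }
  if (!mono(tbl$escalate_le) || !mono(tbl$deescalate_ge)) {
    stop("Boundary table invalid: boundaries must be non-decreasing in n.",
         call. = FALSE)
  }
  tbl
}

#' Read or write a boundary table as CSV
#'
#' The on-disk format is a plain CSV with columns `n`, `escalate_le`,
#' `deescalate_ge`; empty cells mark sample sizes at which the action is
#' never taken.  Externally published tables (including printed rows that
#' deviate from the rule-derived table) can be loaded verbatim, as long as
#' they satisfy the structural invariants (monotone boundaries,
#' `escalate_le < deescalate_ge <= n`).
#'
#' @param path File path.
#' @param table An `ei_boundary_table` (or plain data frame with the three
#'   columns).
#' @return `read_boundary_table()` an `ei_boundary_table`;
#'   `write_boundary_table()` the input, invisibly.
#' @export
read_boundary_table <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    n = readr::col_integer(),
    escalate_le = readr::col_integer(),
    deescalate_ge = readr::col_integer()
  ))
  tbl <- validate_boundary_table(tibble::as_tibble(tbl))
  class(tbl) <- c("ei_boundary_table", class(tbl))
  tbl
}

#' @rdname read_boundary_table
#' @export
write_boundary_table <- function(table, path) {
  tbl <- validate_boundary_table(tibble::as_tibble(table))
  readr::write_csv(tbl[c("n", "escalate_le", "deescalate_ge")], path, na = "")
  invisible(table)
}

boundary_row <- function(table, n) {
  i <- match(n, table$n)
  if (is.na(i)) {
    stop(sprintf(paste0("No boundary row at n = %d; rebuild the table with ",
                        "boundary_table(design, n_max >= %d)."), n, n),
         call. = FALSE)
  }
  list(E = table$escalate_le[i], D = table$deescalate_ge[i])
}

#' @export
print.ei_boundary_table <- function(x, ...) {
  d <- attr(x, "design")
  if (!is.null(d)) {
    cat("<ei_boundary_table> ", d$family, ", target ", d$target, "\n", sep = "")
  }
  NextMethod()
}

#' Plot a boundary table
#'
#' Step plot of the escalation and de-escalation DLT-count boundaries
#' against the number of patients treated, with the target rate shown as a
#' reference line.
#'
#' @param object An `ei_boundary_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ei_boundary_table <- function(object, ...) {
  d <- attr(object, "design")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("escalate_le", "deescalate_ge"),
    names_to = "boundary", values_to = "dlt"
  )
  long$boundary <- factor(long$boundary, c("escalate_le", "deescalate_ge"),
                          c("escalate if DLTs ≤", "de-escalate if DLTs ≥"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$n, .data$dlt,
                                          colour = .data$boundary)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 1) +
    ggplot2::labs(x = "patients treated at current dose", y = "DLT count",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(d)) {
    p <- p + ggplot2::geom_abline(slope = d$target, intercept = 0,
                                  linetype = "dashed", colour = "grey50")
  }
  p
}
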
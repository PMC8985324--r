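#' Calendar days saved by an early stop
#'
#' Projects the completion date of the full MTD-estimation phase — the
#' enrollment time of the last planned patient plus the assessment window
#' — under a fixed accrual spacing, and returns the time between the early
#' identification instant and that projection.  With one patient pending
#' at `t_last_enroll` days of follow-up, the next patient would enroll
#' `spacing - t_last_enroll` days from now, the remaining patients follow
#' at `spacing`-day intervals, and the last of them is observed for the
#' full window.
#'
#' @param n_remaining Patients not yet enrolled at the decision instant.
#' @param spacing Days between consecutive enrollments.
#' @param window Assessment window, days.
#' @param t_last_enroll Days since the most recent enrollment (0 if the
#'   decision coincides with an enrollment).
#' @return Days saved (0 when the trial is already complete).
#' @examples
#' days_saved(6, spacing = 60, window = 70, t_last_enroll = 35)  # 395
#' days_saved(3, spacing = 60, window = 70, t_last_enroll = 35)  # 215
#' @export
days_saved <- function(n_remaining, spacing, window, t_last_enroll = 0) {
  stopifnot(n_remaining >= 0, spacing > 0, window > 0, t_last_enroll >= 0)
  if (n_remaining == 0) {
    return(max(window - t_last_enroll, 0))
  }
  stopifnot(t_last_enroll <= spacing)
  (spacing - t_last_enroll) + (n_remaining - 1) * spacing + window
}

#' Read an interim trial state from JSON
#'
#' The document describes the dose the next cohort would receive:
#' ```json
#' {"N": 30, "treated": 24, "window": 70,
#'  "current_dose": {"n": 3, "n_dlt": 0, "n_nodlt": 2,
#'                   "pending_days": [35]},
#'  "dose_position": "maximum"}
#' ```
#' `pending_days` are DLT-free follow-up times in the same units as
#' `window`.
#'
#' @param path Path to the JSON file.
#' @return A list with elements `N`, `treated`, `r`, `window`, `state` (a
#'   [dose_state()]), and `dose_position`.
#' @export
read_interim_state <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("N", "treated", "window", "current_dose", "dose_position")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop("Interim state is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cd <- doc$current_dose
  pend <- pending_fraction(as.numeric(cd$pending_days %||% numeric()),
                           doc$window)
  st <- dose_state(cd$n_dlt, cd$n_nodlt, pend)
  if (!is.null(cd$n) && st$n != cd$n) {
    stop("Inconsistent interim state: n = ", cd$n, " but tallies sum to ",
         st$n, ".", call. = FALSE)
  }
  list(N = doc$N, treated = doc$treated, r = doc$N - doc$treated,
       window = doc$window, state = st,
       dose_position = match.arg(doc$dose_position,
                                 c("interior", "minimum", "maximum")))
}

#' Interim early-identification report
#'
#' Computes, for each requested design, the dose-retainment probability of
#' the supplied interim state and the early-identification verdict, plus
#' the projected days saved when an accrual spacing is given and the
#' verdict is "stop".
#'
#' @param interim An interim state list from [read_interim_state()], or a
#'   path to the JSON document.
#' @param designs Character vector of design families
#'   (`"mTPI"`, `"Keyboard"`, `"BOIN"`).
#' @param target Target DLT rate.
#' @param config An [ei_config()].
#' @param accrual_spacing Optional days between enrollments, enabling the
#'   days-saved projection.
#' @param t_last_enroll Days since the most recent enrollment, for the
#'   projection (defaults to the largest pending follow-up time, the
#'   usual case of a decision taken mid-assessment).
#' @return A tibble of class `"ei_interim_report"`: one row per design
#'   with the retainment components, verdict, threshold, and `days_saved`.
#' @examples
#' path <- tempfile(fileext = ".json")
#' jsonlite::write_json(list(N = 30, treated = 24, window = 70,
#'   current_dose = list(n = 3, n_dlt = 0, n_nodlt = 2, pending_days = 35),
#'   dose_position = "maximum"), path, auto_unbox = TRUE)
#' report_interim(path, accrual_spacing = 60)
#' @export
report_interim <- function(interim, designs = c("mTPI", "Keyboard", "BOIN"),
                           target = 0.3, config = ei_config(),
                           accrual_spacing = NULL, t_last_enroll = NULL) {
  if (is.character(interim)) interim <- read_interim_state(interim)
  st <- interim$state
  if (is.null(t_last_enroll)) {
    t_last_enroll <- if (length(st$pending)) {
      max(st$pending) * interim$window
    } else {
      0
    }
  }
  rows <- purrr::map(designs, function(fam) {
    des <- design_spec(fam, target = target)
    tab <- boundary_table(des, n_max = st$n + interim$r)
    res <- retainment_probability(st, interim$r, tab, config)
    dec <- ei_decision(res, interim$dose_position, config)
    saved <- if (dec$verdict == "stop" && !is.null(accrual_spacing)) {
      days_saved(interim$r, accrual_spacing, interim$window, t_last_enroll)
    } else {
      NA_real_
    }
    tibble::tibble(design = des$family,
                   p_not_deescalate = res$p_not_deescalate,
                   p_escalate = res$p_escalate,
                   p_retain = res$p_retain,
                   statistic = dec$statistic,
                   threshold = dec$threshold,
                   dose_position = interim$dose_position,
                   verdict = dec$verdict,
                   days_saved = saved)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ei_interim_report", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
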
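#' Specify a model-assisted dose-finding design
#'
#' Bundles the interval parameters of one of the three supported
#' model-assisted designs.  `target` is the target DLT (dose-limiting
#' toxicity) rate the trial aims for.  For mTPI and Keyboard the proper
#' dosing interval is `(target - eps1, target + eps2)`; for BOIN the
#' under- and over-dosing anchors `phi1`, `phi2` default to `0.6 * target`
#' and `1.4 * target`, giving the optimal-interval boundaries of
#' [boin_lambdas()].  The decision posterior uses a `Beta(prior_a,
#' prior_b)` prior, flat by default.
#'
#' @param family One of `"mTPI"`, `"Keyboard"`, `"BOIN"` (case-insensitive).
#' @param target Target DLT rate, in (0, 1).
#' @param eps1,eps2 Half-widths of the proper dosing interval (mTPI and
#'   Keyboard); defaults 0.05 each.
#' @param phi1,phi2 BOIN under/over-dosing anchors.
#' @param prior_a,prior_b Beta prior shapes for the decision posterior.
#'
#' @return An object of class `"ei_design"`: a list with the validated
#'   parameters, plus the BOIN lambda boundaries when `family = "BOIN"`.
#' @examples
#' design_spec("BOIN", target = 0.3)
#' design_spec("Keyboard", target = 0.3)
#' @export
design_spec <- function(family = c("mTPI", "Keyboard", "BOIN"),
                        target = 0.3,
                        eps1 = 0.05, eps2 = 0.05,
                        phi1 = 0.6 * target, phi2 = 1.4 * target,
                        prior_a = 1, prior_b = 1) {
  fam <- match.arg(tolower(family[1]), c("mtpi", "keyboard", "boin"))
  family <- c(mtpi = "mTPI", keyboard = "Keyboard", boin = "BOIN")[[fam]]
  stopifnot(target > 0, target < 1, prior_a > 0, prior_b > 0)
  if (family == "BOIN") {
    if (!(0 < phi1 && phi1 < target && target < phi2 && phi2 < 1)) {
      stop("BOIN anchors must satisfy 0 < phi1 < target < phi2 < 1.",
           call. = FALSE)
    }
  } else {
    if (!(target - eps1 > 0 && target + eps2 < 1 && eps1 > 0 && eps2 > 0)) {
      stop("Proper interval (target - eps1, target + eps2) must lie in (0, 1).",
           call. = FALSE)
    }
  }
  out <- list(family = family, target = target,
              eps1 = eps1, eps2 = eps2, phi1 = phi1, phi2 = phi2,
              prior_a = prior_a, prior_b = prior_b)
  if (family == "BOIN") out$lambda <- boin_lambdas(target, phi1, phi2)
  structure(out, class = "ei_design")
}

#' @export
print.ei_design <- function(x, ...) {
  cat("<ei_design> ", x$family, ", target DLT rate ", x$target, "\n", sep = "")
  if (x$family == "BOIN") {
    cat(sprintf("  retainment interval (%.4f, %.4f)\n",
                x$lambda[["lambda_e"]], x$lambda[["lambda_d"]]))
  } else {
    cat(sprintf("  proper dosing interval (%.2f, %.2f)\n",
                x$target - x$eps1, x$target + x$eps2))
  }
  invisible(x)
}

#' BOIN optimal interval boundaries
#'
#' Closed-form escalation/de-escalation rate boundaries of the Bayesian
#' optimal interval design: the interval that minimizes the probability of
#' an incorrect dose-assignment decision when the true rate is `target`
#' versus the under-dosing anchor `phi1` or over-dosing anchor `phi2`.
#'
#' @param target Target DLT rate.
#' @param phi1,phi2 Anchors with `0 < phi1 < target < phi2 < 1`.
#' @return Named numeric vector `c(lambda_e, lambda_d)`; escalate while the
#'   observed DLT rate is strictly below `lambda_e`, de-escalate at or
#'   above `lambda_d`.
#' @examples
#' boin_lambdas(0.30, 0.18, 0.42)  # (0.236, 0.358)
#' @export
boin_lambdas <- function(target, phi1 = 0.6 * target, phi2 = 1.4 * target) {
  if (!(0 < phi1 && phi1 < target && target < phi2 && phi2 < 1)) {
    stop("Require 0 < phi1 < target < phi2 < 1.", call. = FALSE)
  }
  lambda_e <- log((1 - phi1) / (1 - target)) /
    log(target * (1 - phi1) / (phi1 * (1 - target)))
  lambda_d <- log((1 - target) / (1 - phi2)) /
    log(phi2 * (1 - target) / (target * (1 - phi2)))
  c(lambda_e = lambda_e, lambda_d = lambda_d)
}

#' Dose-assignment decision from observed (possibly fractional) counts
#'
#' Applies a design's decision rule to the toxicity tally at the current
#' dose and returns `"escalate"`, `"retain"`, or `"deescalate"`.  The
#' DLT-free count `n_free` may be fractional: in the TITE extension pending
#' patients contribute their elapsed follow-up fraction as partial
#' non-toxicity evidence, and each rule below is evaluated with the
#' effective data `(n_dlt, n_free)`.  With all assessments complete this is
#' exactly the complete-data rule.
#'
#' * **BOIN** compares the imputed rate `n_dlt / (n_dlt + n_free)` with the
#'   lambda boundaries: escalate strictly below `lambda_e`, de-escalate at
#'   or above `lambda_d`.
#' * **mTPI** computes the unit probability mass (interval posterior
#'   probability over interval width) of the under-dosing, proper, and
#'   over-dosing intervals under the posterior
#'   `Beta(prior_a + n_dlt, prior_b + n_free)` and takes the argmax
#'   (ties: retain, then escalate).
#' * **Keyboard** tiles (0, 1) with keys of the proper interval's width,
#'   drops partial-width edge strips, and moves toward the key with
#'   maximal posterior mass (the "strongest key"); ties go to the key
#'   nearer the target key, the target key winning outright.
#'
#' @param n_dlt Number of DLTs at the current dose.
#' @param n_free Effective DLT-free count (completed DLT-free patients plus
#'   summed pending follow-up fractions).
#' @param design An [design_spec()] object.
#' @return Length-1 character: `"escalate"`, `"retain"`, or `"deescalate"`.
#' @examples
#' d <- design_spec("BOIN", 0.3)
#' dose_decision(2, 4, d)  # 2/6 = 0.333, inside (0.236, 0.358): retain
#' @export
dose_decision <- function(n_dlt, n_free, design) {
  stopifnot(inherits(design, "ei_design"), n_dlt >= 0, n_free >= 0)
  if (n_dlt + n_free <= 0) {
    stop("No data at the current dose: n_dlt + n_free must be positive.",
         call. = FALSE)
  }
  switch(design$family,
    BOIN = boin_rule(n_dlt, n_free, design$lambda),
    mTPI = mtpi_rule(n_dlt, n_free, design),
    Keyboard = keyboard_rule(n_dlt, n_free, design)
  )
}

boin_rule <- function(n_dlt, n_free, lambda) {
  rate <- n_dlt / (n_dlt + n_free)
  if (rate < lambda[["lambda_e"]]) "escalate"
  else if (rate >= lambda[["lambda_d"]]) "deescalate"
  else "retain"
}

mtpi_rule <- function(n_dlt, n_free, design) {
  a <- design$prior_a + n_dlt
  b <- design$prior_b + n_free
  lo <- design$target - design$eps1
  hi <- design$target + design$eps2
  upm <- c(
    escalate   = stats::pbeta(lo, a, b) / lo,
    retain     = (stats::pbeta(hi, a, b) - stats::pbeta(lo, a, b)) / (hi - lo),
    deescalate = stats::pbeta(hi, a, b, lower.tail = FALSE) / (1 - hi)
  )
  # ties (measure zero) break toward retain, then escalate
  ord <- c("retain", "escalate", "deescalate")
  ord[which.max(upm[ord])]
}

keyboard_keys <- function(design) {
  w <- design$eps1 + design$eps2
  lo <- design$target - design$eps1
  left <- rev(seq(lo, 0 + 1e-12, by = -w))  # full-width keys only
  left <- left[left >= -1e-9]
  starts <- c(left[-length(left)], seq(lo, 1 - w + 1e-9, by = w))
  starts <- sort(unique(round(starts, 10)))
  starts <- starts[starts >= -1e-9 & starts + w <= 1 + 1e-9]
  tibble::tibble(lower = starts, upper = starts + w)
}

keyboard_rule <- function(n_dlt, n_free, design) {
  keys <- keyboard_keys(design)
  a <- design$prior_a + n_dlt
  b <- design$prior_b + n_free
  mass <- stats::pbeta(keys$upper, a, b) - stats::pbeta(keys$lower, a, b)
  target_key <- which(abs(keys$lower - (design$target - design$eps1)) < 1e-9)
  best <- which(mass >= max(mass) - 1e-12)
  # tie-break: target key wins outright, otherwise the key nearest it
  strongest <- if (target_key %in% best) {
    target_key
  } else {
    best[which.min(abs(best - target_key))]
  }
  if (strongest < target_key) "escalate"
  else if (strongest == target_key) "retain"
  else "deescalate"
}
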
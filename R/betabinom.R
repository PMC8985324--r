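#' Generalized beta-binomial distribution with a fractional number of trials
#'
#' Probability mass and distribution function of the beta-binomial
#' distribution, generalized so that the number of trials `size` may be a
#' non-negative real number.  The mass at an integer count `x` is
#' \deqn{C(b, x) \, B(x + \alpha, b - x + \beta) / B(\alpha, \beta),}
#' with the generalized binomial coefficient
#' \eqn{C(b, x) = \Gamma(b+1) / (\Gamma(x+1)\Gamma(b-x+1))} so that
#' fractional \eqn{b} (trials contributed as partial follow-up, e.g. 6.5
#' future patients) is allowed.  For integer `size` this is the ordinary
#' beta-binomial; for fractional `size` the masses need not sum to one and
#' the function is used only through differences of the distribution
#' function, which is how the dose-retainment probability consumes it.
#'
#' Everything is evaluated in log-gamma space with a single final
#' exponentiation, so small shape parameters and `size` up to a few dozen
#' do not underflow.
#'
#' @param x,q Vector of counts (`x`) or count bounds (`q`).  `q` may be
#'   negative, giving probability 0; non-integer `q` is floored.
#' @param size Number of trials, a single non-negative real.
#' @param shape1,shape2 Positive beta shape parameters (prior toxicity /
#'   prior non-toxicity pseudo-counts).
#'
#' @return `dbbinom()` the mass at each `x`; `pbbinom()` the lower tail
#'   \eqn{\sum_{k=0}^{\lfloor q \rfloor}} of the mass.
#'
#' @examples
#' dbbinom(0, size = 7, shape1 = 3, shape2 = 5)   # 105/1092
#' pbbinom(2, size = 7, shape1 = 3, shape2 = 5)   # 0.500
#' pbbinom(3, size = 6.5, shape1 = 0.5, shape2 = 3)
#' @export
dbbinom <- function(x, size, shape1, shape2) {
  check_bb_args(size, shape1, shape2)
  if (any(x < 0) || any(x != floor(x))) {
    stop("`x` must contain non-negative integers.", call. = FALSE)
  }
  out <- numeric(length(x))
  # beyond the support: for integer size, x > size has mass 0; for
  # fractional size the summand is defined while both gamma arguments
  # (size - x + 1 in the coefficient, size - x + shape2 in the beta
  # kernel) remain positive
  ok <- (size - x + shape2) > 0 & (size - x + 1) > 0 &
    !(is_whole(size) & x > size)
  xv <- x[ok]
  out[ok] <- exp(
    lgamma(size + 1) - lgamma(xv + 1) - lgamma(size - xv + 1) +
      lbeta(xv + shape1, size - xv + shape2) - lbeta(shape1, shape2)
  )
  out
}

#' @rdname dbbinom
#' @export
pbbinom <- function(q, size, shape1, shape2) {
  check_bb_args(size, shape1, shape2)
  vapply(q, function(a) {
    a <- floor(a)
    if (a < 0) return(0)
    hi <- min(a, ceiling(size))  # dbbinom() zeroes terms outside the support
    sum(dbbinom(0:hi, size, shape1, shape2))
  }, numeric(1))
}

check_bb_args <- function(size, shape1, shape2) {
  stopifnot(length(size) == 1, length(shape1) == 1, length(shape2) == 1)
  if (!is.finite(size) || size < 0) {
    stop("`size` must be a non-negative real number.", call. = FALSE)
  }
  if (!is.finite(shape1) || !is.finite(shape2) || shape1 <= 0 || shape2 <= 0) {
    stop("`shape1` and `shape2` must be positive.", call. = FALSE)
  }
  invisible(NULL)
}

is_whole <- function(x, tol = 1e-9) abs(x - round(x)) < tol
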
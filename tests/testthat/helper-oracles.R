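# Independent oracles used across the suite.

# direct (non-log) evaluation of the generalized beta-binomial mass
bb_pmf_direct <- function(k, b, a, bt) {
  gamma(b + 1) / (gamma(k + 1) * gamma(b - k + 1)) *
    beta(k + a, b - k + bt) / beta(a, bt)
}

bb_cdf_direct <- function(q, b, a, bt) {
  if (q < 0) return(0)
  sum(vapply(0:floor(q), bb_pmf_direct, numeric(1), b = b, a = a, bt = bt))
}

# sampling oracle for integer trials: p ~ Beta(a, bt), X ~ Binomial(b, p)
bb_cdf_mc <- function(q, b, a, bt, n_draws = 1e6) {
  p <- rbeta(n_draws, a, bt)
  x <- rbinom(n_draws, b, p)
  mean(x <= q)
}

# interval posterior masses by numerical integration of the beta density
beta_mass_quad <- function(lo, hi, a, b) {
  stats::integrate(function(p) stats::dbeta(p, a, b), lo, hi,
                   rel.tol = 1e-10)$value
}

# brute-force mTPI decision via quadrature UPMs
mtpi_oracle <- function(n_dlt, n, target = 0.3, eps = 0.05) {
  a <- 1 + n_dlt
  b <- 1 + n - n_dlt
  upm <- c(
    escalate = beta_mass_quad(0, target - eps, a, b) / (target - eps),
    retain = beta_mass_quad(target - eps, target + eps, a, b) / (2 * eps),
    deescalate = beta_mass_quad(target + eps, 1, a, b) / (1 - target - eps)
  )
  names(upm)[which.max(upm)]
}

# brute-force Keyboard decision via quadrature key masses
keyboard_oracle <- function(n_dlt, n, target = 0.3, eps = 0.05) {
  w <- 2 * eps
  starts <- seq(target - eps - w * floor((target - eps) / w), 1 - w, by = w)
  starts <- round(starts, 10)
  starts <- starts[starts >= 0 & starts + w <= 1 + 1e-9]
  mass <- vapply(starts, function(lo) {
    beta_mass_quad(lo, lo + w, 1 + n_dlt, 1 + n - n_dlt)
  }, numeric(1))
  tgt <- which(abs(starts - (target - eps)) < 1e-9)
  i <- which.max(mass)
  if (i < tgt) "escalate" else if (i == tgt) "retain" else "deescalate"
}

# brute-force MTD pick: enumerate all monotone fits is overkill; instead
# check the PAVA fit against stats::isoreg on equal weights and against
# direct pooled means on hand-constructed cases in the tests.

tbcrc_window <- 70

# standard simulation conditions used by several property tests
smoke_scenario <- function() scenario(c(0.14, 0.30, 0.45, 0.55, 0.65, 0.75))
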
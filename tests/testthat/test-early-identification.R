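boin_table18 <- boundary_table(design_spec("BOIN", 0.3), 18)

test_that("pending fractions and effective counts follow the definitions", {
  expect_equal(pending_fraction(35, 70), 0.5)
  expect_equal(pending_fraction(70, 70), 1)
  expect_equal(pending_fraction(0, 70), 0)
  expect_error(pending_fraction(80, 70), "t_obs <= t_window")

  st <- dose_state(3, 4, c(2 / 3, 1 / 3))
  eff <- effective_counts(st)
  expect_equal(eff$n_pend, 1)
  expect_equal(eff$n_e, 5)
  expect_equal(effective_counts(dose_state(1, 2))$n_e, 2)
  expect_equal(effective_counts(dose_state(0, 2, 0.5))$n_e, 2.5)
  expect_equal(dose_state(3, 4, c(2 / 3, 1 / 3))$n, 9L)
  expect_error(dose_state(1, 1, 1.0), "\\[0, 1\\)")
})

test_that("effective future-trial counts coincide across conventions on the worked states", {
  st <- dose_state(3, 4, c(2 / 3, 1 / 3))
  expect_equal(future_trials(6, st, "remaining_fraction"), 7)
  expect_equal(future_trials(6, st, "literal"), 7)
  st2 <- dose_state(0, 2, 0.5)
  expect_equal(future_trials(6, st2, "remaining_fraction"), 6.5)
  expect_equal(future_trials(6, st2, "literal"), 6.5)
  expect_equal(future_trials(5, dose_state(1, 2)), 5)
  expect_error(future_trials(-1, st), "r >= 0")
})

test_that("the worked retainment example reproduces: 0.500 - 0.096 = 0.404", {
  st <- dose_state(3, 4, c(2 / 3, 1 / 3))
  res <- retainment_probability(st, 6, boin_table18)
  expect_equal(res$p_not_deescalate, 0.500, tolerance = 1e-3)
  expect_equal(res$p_escalate, 0.096, tolerance = 2e-3)
  expect_equal(res$p_retain, 0.404, tolerance = 1e-3)
  expect_equal(res$boundary_e, 3L)  # E at n + r = 15
  expect_equal(res$boundary_d, 6L)
  expect_equal(ei_decision(res, "interior")$verdict, "stop")
})

test_that("a larger remaining cohort lowers the retainment probability", {
  st <- dose_state(3, 4, c(2 / 3, 1 / 3))
  tab <- boundary_table(design_spec("BOIN", 0.3), 21)
  r6 <- retainment_probability(st, 6, tab)
  r9 <- retainment_probability(st, 9, tab)
  expect_lt(r9$p_retain, r6$p_retain)
  expect_equal(ei_decision(r9, "interior")$verdict, "continue")
})

test_that("zero-count correction applies to both shapes and matches the TBCRC state", {
  st <- dose_state(0, 2, pending_fraction(35, tbcrc_window))
  tab <- boundary_table(design_spec("BOIN", 0.3), 9)
  res <- retainment_probability(st, 6, tab)
  expect_equal(res$n_e, 2.5)
  expect_equal(res$r_pend, 6.5)
  # shapes (0.5, 3.0) over 6.5 trials, bound D - 1 = 3
  expect_equal(res$p_not_deescalate, bb_cdf_direct(3, 6.5, 0.5, 3.0),
               tolerance = 1e-10)
  expect_equal(res$p_not_deescalate, 0.936, tolerance = 1e-3)
})

test_that("counts already past the de-escalation boundary give zero retainment", {
  st <- dose_state(6, 3)
  res <- retainment_probability(st, 6, boin_table18)  # D_15 = 6, bound < 0
  expect_equal(res$p_not_deescalate, 0)
  expect_equal(res$p_retain, 0)
})

test_that("sentinel boundaries give the degenerate probabilities", {
  tab <- tibble::tibble(n = 1:12, escalate_le = NA_integer_,
                        deescalate_ge = NA_integer_)
  class(tab) <- c("ei_boundary_table", class(tab))
  res <- retainment_probability(dose_state(1, 2), 6, tab)
  expect_equal(res$p_not_deescalate, 1)
  expect_equal(res$p_escalate, 0)
  expect_equal(res$p_retain, 1)
})

test_that("a missing boundary row points the user at the table", {
  expect_error(retainment_probability(dose_state(3, 6), 12, boin_table18),
               "rebuild the table")
})

test_that("a pending patient at the end of the window equals a completed one", {
  for (eps in c(1e-6, 1e-9)) {
    st_pending <- dose_state(2, 3, c(0.4, 1 - eps))
    st_complete <- dose_state(2, 4, 0.4)
    a <- retainment_probability(st_pending, 6, boin_table18)
    b <- retainment_probability(st_complete, 6, boin_table18)
    expect_equal(a$p_retain, b$p_retain, tolerance = max(1e-9, 10 * eps))
    expect_equal(a$r_pend, b$r_pend, tolerance = max(1e-9, 10 * eps))
  }
})

test_that("no remaining patients collapses to a point mass on the current decision", {
  # 2/6 observed: retain region for BOIN at n = 6 (E = 1, D = 3)
  res <- retainment_probability(dose_state(2, 4), 0, boin_table18)
  expect_equal(res$p_not_deescalate, 1)
  expect_equal(res$p_escalate, 0)
  # 4/6 observed: beyond D - 1
  res2 <- retainment_probability(dose_state(4, 2), 0, boin_table18)
  expect_equal(res2$p_not_deescalate, 0)
})

test_that("escalation never exceeds not-de-escalation across interim states", {
  set.seed(7)
  for (i in 1:50) {
    n_dlt <- sample(0:4, 1)
    n_nodlt <- sample(0:5, 1)
    pend <- runif(sample(0:3, 1))
    st <- dose_state(n_dlt, n_nodlt, pend)
    r <- sample(0:(18 - st$n), 1)
    res <- retainment_probability(st, r, boin_table18)
    expect_gte(res$p_not_deescalate + 1e-12, res$p_escalate)
    expect_gte(res$p_retain, -1e-12)
  }
})

test_that("boundary-dose rules and unreachable thresholds behave as specified", {
  st <- dose_state(0, 2, 0.5)
  tab <- boundary_table(design_spec("BOIN", 0.3), 9)
  res <- retainment_probability(st, 6, tab)
  expect_equal(ei_decision(res, "maximum")$verdict, "stop")       # 0.936 > 0.8
  expect_equal(ei_decision(res, "minimum")$verdict, "continue")   # 1 - p_esc
  cfg_off <- suppressWarnings(ei_config(threshold = 1.1))
  for (pos in c("interior", "minimum", "maximum")) {
    expect_equal(ei_decision(res, pos, cfg_off)$verdict, "continue")
  }
})
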
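boin <- design_spec("BOIN", 0.3)

test_that("TITE decisions use fractional follow-up and reduce to complete data", {
  # imputed rate 3/8 = 0.375 >= lambda_d
  expect_equal(dose_decision(3, 4 + 2 / 3 + 1 / 3, boin), "deescalate")
  expect_equal(dose_decision(2, 4, boin), "retain")
  # continuity: near-complete pending equals complete data for all designs
  for (fam in c("mTPI", "Keyboard", "BOIN")) {
    d <- design_spec(fam, 0.3)
    for (k in 0:3) {
      eps <- 1e-9
      expect_equal(dose_decision(k, (3 - k) * (1 - eps), d),
                   dose_decision(k, 3 - k, d))
    }
  }
})

test_that("accrual suspension triggers below the resolved-outcome fraction", {
  expect_equal(suspension_check(0, 3, 0.5), "suspend")
  expect_equal(suspension_check(2, 3, 0.5), "enroll")
  expect_equal(suspension_check(0, 3, 0), "enroll")
})

test_that("dose elimination follows the posterior overdose rule", {
  # Beta(4, 1): P(p > 0.3) = 1 - 0.3^4
  expect_equal(pbeta(0.3, 4, 1, lower.tail = FALSE), 1 - 0.3^4)
  expect_equal(elimination_check(3, 0, 3, 0.3), "eliminate")
  expect_equal(elimination_check(0, 3, 3, 0.3), "keep")
  expect_equal(elimination_check(2, 0, 2, 0.3, min_n = 3), "keep")
})

test_that("dose transitions never skip and never enter eliminated levels", {
  elim <- rep(FALSE, 6)
  expect_equal(next_dose(6, "escalate", elim, 6), 6L)
  expect_equal(next_dose(1, "deescalate", elim, 6), 1L)
  expect_equal(next_dose(3, "escalate", c(FALSE, FALSE, FALSE, TRUE,
                                          FALSE, FALSE), 6), 3L)
  expect_equal(next_dose(3, "escalate", elim, 6), 4L)
  expect_equal(next_dose(3, "retain", elim, 6), 3L)
})

test_that("weighted PAVA pools violators and MTD selection matches hand cases", {
  expect_equal(eimtd:::pava(c(0.1, 0.3, 0.2), rep(1, 3)),
               c(0.1, 0.25, 0.25))
  expect_equal(eimtd:::pava(c(0.1, 0.2, 0.3), rep(2, 3)), c(0.1, 0.2, 0.3))
  # weighted pooling: (0.4 * 3 + 0.1 * 1) / 4
  expect_equal(eimtd:::pava(c(0.4, 0.1), c(3, 1)), rep(0.325, 2))
  # agreement with stats::isoreg on equal weights
  set.seed(11)
  for (i in 1:20) {
    y <- runif(6)
    expect_equal(eimtd:::pava(y, rep(1, 6)), stats::isoreg(y)$yf,
                 tolerance = 1e-10)
  }
  expect_equal(select_mtd(c(3, 6, 6), c(0, 1, 3), 0.3), 2L)
  expect_equal(select_mtd(c(0, 0, 0), c(0, 0, 0), 0.3), NA_integer_)
  expect_equal(select_mtd(c(6, 6), c(2, 2), 0.3,
                          eliminated = c(FALSE, TRUE)), 1L)
})

test_that("a tolerable top dose is escalated to and early-identified there", {
  cfg <- trial_config(boin, n_doses = 4, n = 24, ei = ei_config())
  tr <- run_trial(cfg, scenario(c(0, 0, 0, 0)), seed = 1)
  expect_true(tr$stopped_early)
  expect_equal(tr$selected_mtd, 4L)
  expect_true(any(tr$events$event == "ei_stop"))
})

test_that("an overly toxic lowest dose terminates the trial with no MTD", {
  cfg <- trial_config(boin, n_doses = 4, n = 24)
  tr <- run_trial(cfg, scenario(c(1, 1, 1, 1), overdose_margin = 0), seed = 1)
  expect_equal(tr$stop_reason, "terminated")
  expect_true(is.na(tr$selected_mtd))
  expect_true(all(tr$eliminated))
})

test_that("an unreachable EI threshold reproduces the EI-disabled trial exactly", {
  sc <- smoke_scenario()
  cfg_off <- trial_config(boin, n = 36)
  cfg_unreachable <- trial_config(boin, n = 36,
                                  ei = suppressWarnings(ei_config(1.01)))
  for (seed in 1:5) {
    set.seed(seed)
    latent <- paired_latent_patients(sc, cfg_off)
    a <- run_trial(cfg_off, sc, latent = latent)
    b <- run_trial(cfg_unreachable, sc, latent = latent)
    expect_identical(a, b)
  }
})

test_that("a vanishing window makes TITE conduct equal the plain design", {
  sc <- scenario(c(0.05, 0.15, 0.3, 0.45, 0.6, 0.7))
  cfg_tite <- trial_config(boin, n = 36, window = 1e-9)
  cfg_plain <- trial_config(boin, n = 36, window = 1e-9, tite = FALSE)
  for (seed in 1:5) {
    set.seed(seed)
    latent <- paired_latent_patients(sc, cfg_tite)
    a <- run_trial(cfg_tite, sc, latent = latent)
    b <- run_trial(cfg_plain, sc, latent = latent)
    expect_equal(a$selected_mtd, b$selected_mtd)
    expect_equal(a$dose_n, b$dose_n)
    expect_equal(a$events$event, b$events$event)
  }
})

test_that("trial records satisfy their structural invariants across seeds", {
  sc <- smoke_scenario()
  cfg <- trial_config(boin, n = 36, ei = ei_config())
  for (seed in 1:20) {
    tr <- run_trial(cfg, sc, seed = seed)
    expect_true(all(diff(tr$events$time) >= -1e-12))
    expect_lte(tr$n_treated, 36)
    expect_gte(tr$duration, max(tr$events$time) - 1e-12)
    if (!is.na(tr$selected_mtd)) {
      expect_false(tr$eliminated[tr$selected_mtd])
      expect_gt(tr$dose_n[tr$selected_mtd], 0)
    }
    expect_equal(sum(tr$dose_n), tr$n_treated)
  }
})

test_that("tidiers expose the trial as tibbles", {
  cfg <- trial_config(boin, n_doses = 4, n = 12)
  tr <- run_trial(cfg, scenario(c(0.05, 0.15, 0.3, 0.5)), seed = 3)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$n), tr$n_treated)
  gl <- glance(tr)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("selected_mtd", "stopped_early", "stop_reason",
                     "n_treated", "duration"))
})
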
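test_that("terminal slope is exact on a single exponential and matches beta on the model", {
  tt <- c(1, 2, 4, 8, 12)
  expect_equal(fit_lambda_z(tt, 100 * exp(-0.1 * tt))$lambda_z, 0.1,
               tolerance = 1e-12)
  # noise-free two-compartment tail sampled late
  p <- iv_params()
  cc <- conc_iv(p, dose_event(5, "iv_bolus"), c(4, 8, 24))
  lz <- fit_lambda_z(c(4, 8, 24), cc)
  expect_equal(lz$lambda_z, macro_from_micro(p)$beta, tolerance = 0.02)
})

test_that("degenerate tails are refused", {
  expect_error(fit_lambda_z(c(1, 2, 4), c(50, 50, 50)), "no terminal phase")
  expect_error(fit_lambda_z(c(1, 2, 4), c(10, 20, 40)), "no terminal phase")
  expect_error(fit_lambda_z(c(1, 2), c(10, 5)), "fewer than 3")
})

test_that("trapezoidal AUC matches closed-form segment values", {
  expect_equal(auc_trapezoid(c(0, 1), c(100, 100), "linear")$auc, 100)
  expect_equal(auc_trapezoid(c(0, 1), c(100, 100))$auc, 100)
  seg <- auc_trapezoid(c(0, 1), c(100, 50))
  expect_equal(seg$auc, 50 / log(2), tolerance = 1e-12)
  # linear rule overestimates on convex exponential decay
  tt <- c(0, 1, 2, 4, 8)
  cc <- 100 * exp(-0.5 * tt)
  expect_gt(auc_trapezoid(tt, cc, "linear")$auc, auc_trapezoid(tt, cc)$auc)
  # log-down AUMC on an exact exponential segment
  lam <- log(100 / 50)
  expect_equal(seg$aumc, (0 * 100 - 1 * 50) / lam + (100 - 50) / lam^2,
               tolerance = 1e-12)
})

test_that("NCA on a noise-free one-compartment profile recovers CL and Vd", {
  tt <- seq(0.25, 48, by = 0.25)
  cc <- 1000 * 5 / 2 * exp(-0.1 * tt)
  res <- nca_summary(tt, cc, dose = 5, route = "iv_bolus")
  expect_equal(res$cl, 0.2, tolerance = 0.01)
  expect_equal(res$vd, 2, tolerance = 0.01)
  expect_equal(res$lambda_z, 0.1, tolerance = 1e-6)
  # internal identities hold exactly
  expect_equal(res$t_half * res$lambda_z, log(2))
  expect_equal(res$cl, res$vd * res$lambda_z)
  expect_equal(res$cl, 1000 * 5 / res$auc_0_inf)
})

test_that("dense noise-free NCA is an unbiased oracle for the two-compartment model", {
  p <- iv_params()
  tt <- c(seq(0.05, 24, by = 0.05), seq(25, 120, by = 1))
  cc <- conc_iv(p, dose_event(5, "iv_bolus"), tt)
  res <- nca_summary(tt, cc, dose = 5, route = "iv_bolus")
  expect_equal(res$lambda_z, macro_from_micro(p)$beta, tolerance = 0.02)
  expect_equal(res$cl, 3.60 * 0.17, tolerance = 0.02)
  expect_equal(res$auc_0_inf, 1000 * 5 / (3.60 * 0.17), tolerance = 0.005)
  # oral route: apparent clearance and terminal slope
  po <- oral_params()
  cco <- conc_oral(po, dose_event(100, "oral"), tt)
  reso <- nca_summary(tt, cco, dose = 100, route = "oral")
  expect_equal(reso$cl, 22.20 * 0.43, tolerance = 0.02)
  expect_equal(reso$lambda_z, macro_from_micro(po)$beta, tolerance = 0.02)
  expect_gt(reso$tmax, 0)
})

test_that("doubling the dose doubles AUC and leaves clearance unchanged", {
  tt <- seq(0.25, 72, by = 0.25)
  p <- iv_params()
  r1 <- nca_summary(tt, conc_iv(p, dose_event(5, "iv_bolus"), tt), 5, "iv_bolus")
  r2 <- nca_summary(tt, conc_iv(p, dose_event(10, "iv_bolus"), tt), 10, "iv_bolus")
  expect_equal(r2$auc_0_inf, 2 * r1$auc_0_inf)
  expect_equal(r2$cl, r1$cl)
})

test_that("a simulated cohort yields NCA results satisfying the invariants", {
  sim <- simulate_population(default_iv_design(), default_iv_model(), seed = 31)
  tab <- nca_dataset(sim)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$auc_0_inf >= tab$auc_0_t))
  expect_true(all(tab$auc_0_t > 0))
  expect_true(all(tab$lambda_z > 0))
  expect_equal(tab$t_half, log(2) / tab$lambda_z)
  expect_equal(tab$cl, tab$vd * tab$lambda_z)
  expect_true(is.data.frame(attr(tab, "summary")))
})

test_that("bioavailability is the dose-normalized AUC ratio", {
  expect_equal(bioavailability(6519, 100, 6076, 5),
               (6519 / 100) / (6076 / 5))
  expect_equal(round(100 * bioavailability(6519, 100, 6076, 5), 1), 5.4)
  expect_equal(bioavailability(500, 10, 250, 5), 1)
})

test_that("NCA bioavailability recovers a known simulated F", {
  f_true <- 0.3
  p <- iv_params()
  po <- micro_params_oral(p$V / f_true, p$k10, p$k12, p$k21, ka = 1.5)
  tt <- c(seq(0.05, 24, by = 0.05), seq(25, 200, by = 0.5))
  auc_iv <- nca_summary(tt, conc_iv(p, dose_event(5, "iv_bolus"), tt),
                        5, "iv_bolus")$auc_0_inf
  auc_po <- nca_summary(tt, conc_oral(po, dose_event(100, "oral"), tt),
                        100, "oral")$auc_0_inf
  expect_equal(bioavailability(auc_po, 100, auc_iv, 5), f_true,
               tolerance = 0.02)
})
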
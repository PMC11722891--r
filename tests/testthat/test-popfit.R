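test_that("a single noise-free rich profile is fully identifying", {
  des <- study_design("iv_bolus", 5,
                      sampling_times = c(0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6,
                                         8, 12, 16, 24, 36, 48),
                      n_subjects = 1, lloq = NA)
  mod <- population_model("iv_2cmt", iv_typical, omega = 0, b = 1e-6)
  sim <- simulate_population(des, mod, seed = 2)
  fit <- saem_fit(sim, "iv_2cmt",
                  fit_settings(n_burn = 150, n_smooth = 100, n_ll = 100,
                               seed = 5, init_b = 0.05))
  expect_equal(unname(fit$theta_hat), unname(iv_typical), tolerance = 0.01)
})

test_that("SAEM recovers typical values and shrinks omega on IIV-free data", {
  des <- default_iv_design(n_subjects = 50)
  mod <- population_model("iv_2cmt", iv_typical, omega = 0, b = 0.22)
  sim <- simulate_population(des, mod, seed = 3)
  fit <- saem_fit_ensemble(sim, "iv_2cmt", fit_settings(seed = 5, n_ll = 300),
                           n_runs = 3)
  expect_equal(unname(fit$theta_hat), unname(iv_typical), tolerance = 0.05)
  expect_true(all(fit$omega_hat < 0.15))
})

test_that("the fit is bitwise deterministic given seed, settings and data", {
  sim <- simulate_population(default_iv_design(10), default_iv_model(), seed = 4)
  f1 <- saem_fit(sim, "iv_2cmt", quick_settings(seed = 6))
  f2 <- saem_fit(sim, "iv_2cmt", quick_settings(seed = 6))
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_identical(f1$omega_hat, f2$omega_hat)
  expect_identical(f1$b_hat, f2$b_hat)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
})

test_that("relative standard errors shrink as the cohort grows", {
  mod <- default_iv_model()
  f_small <- saem_fit(simulate_population(default_iv_design(6), mod, seed = 8),
                      "iv_2cmt", quick_settings(seed = 5))
  f_large <- saem_fit(simulate_population(default_iv_design(60), mod, seed = 8),
                      "iv_2cmt", quick_settings(seed = 5))
  th <- names(f_small$theta_hat)
  expect_true(all(f_small$rse_pct[th] > f_large$rse_pct[th]))
})

test_that("importance-sampling likelihood collapses correctly as omega -> 0", {
  des <- default_iv_design(n_subjects = 12)
  mod <- population_model("iv_2cmt", iv_typical, omega = 1e-5, b = 0.22)
  sim <- simulate_population(des, mod, seed = 9)
  pf <- population_fit(mod, sim)
  ll <- log_likelihood_is(pf, n_samples = 2000, seed = 10)
  # collapsed-integral oracle: product of observation densities at the
  # typical parameters
  obs <- sim[sim$EVID == 0L & sim$CENS == 0L, ]
  f <- conc_iv(iv_params(), dose_event(5, "iv_bolus"), obs$TIME)
  direct <- sum(stats::dnorm(obs$DV, f, 0.22 * f, log = TRUE))
  expect_lt(abs(ll$ll - direct), max(3 * ll$se, 0.5))
})

test_that("duplicating every subject doubles the log-likelihood", {
  des <- default_iv_design(n_subjects = 8)
  sim <- simulate_population(des, default_iv_model(), seed = 11)
  dup <- sim
  dup$ID <- dup$ID + 100L
  both <- rbind(sim, dup)
  class(both) <- class(sim)
  mod <- default_iv_model()
  ll1 <- log_likelihood_is(population_fit(mod, sim), 3000, seed = 12)
  ll2 <- log_likelihood_is(population_fit(mod, both), 3000, seed = 12)
  expect_lt(abs(ll2$ll - 2 * ll1$ll), 3 * sqrt(ll2$se^2 + 4 * ll1$se^2) + 0.5)
})

test_that("nesting: the richer model cannot have materially lower likelihood", {
  sim <- simulate_population(default_iv_design(20), default_iv_model(), seed = 13)
  f2 <- saem_fit(sim, "iv_2cmt", quick_settings(seed = 5))
  f1 <- saem_fit(sim, "iv_1cmt", quick_settings(seed = 5))
  expect_gt(f2$log_likelihood,
            f1$log_likelihood - 3 * sqrt(f1$ll_se^2 + f2$ll_se^2))
  cmp <- compare_models(list(cmt2 = f2, cmt1 = f1),
                        nested = list(c("cmt2", "cmt1")))
  expect_equal(cmp$lrt$df, 4)
  expect_gte(cmp$lrt$statistic, 0)
  expect_equal(cmp$criteria$delta_aic[which.min(cmp$criteria$aic)], 0)
})

test_that("comparing a fit with itself gives zero deltas", {
  sim <- simulate_population(default_iv_design(8), default_iv_model(), seed = 14)
  f <- saem_fit(sim, "iv_2cmt", quick_settings(seed = 5))
  cmp <- compare_models(list(a = f, b = f))
  expect_equal(cmp$criteria$delta_aic, c(0, 0))
  expect_equal(cmp$criteria$delta_bic, c(0, 0))
})

test_that("AIC and BIC follow their definitions", {
  sim <- simulate_population(default_iv_design(9), default_iv_model(), seed = 15)
  f <- saem_fit(sim, "iv_2cmt", quick_settings(seed = 5))
  expect_equal(f$aic, -2 * f$log_likelihood + 2 * f$n_par)
  expect_equal(f$bic, -2 * f$log_likelihood + f$n_par * log(9))
})

test_that("subjects without usable observations are rejected", {
  sim <- simulate_population(default_iv_design(4), default_iv_model(), seed = 16)
  sim$CENS[sim$ID == 2 & sim$EVID == 0L] <- 1L
  expect_error(saem_fit(sim, "iv_2cmt", quick_settings()), "uncensored")
})
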
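test_that("variability switched off reproduces the structural model exactly", {
  des <- default_iv_design(n_subjects = 3)
  mod <- population_model("iv_2cmt", iv_typical, omega = 0, b = 1e-12)
  sim <- simulate_population(des, mod, seed = 5)
  obs <- sim[sim$EVID == 0L, ]
  ref <- conc_iv(iv_params(), dose_event(5, "iv_bolus"), des$sampling_times)
  for (id in 1:3)
    expect_equal(obs$DV[obs$ID == id], ref, tolerance = 1e-9)
})

test_that("simulation is deterministic under a fixed seed, including the CSV bytes", {
  des <- default_oral_design()
  mod <- default_oral_model()
  s1 <- simulate_population(des, mod, seed = 99)
  s2 <- simulate_population(des, mod, seed = 99)
  expect_identical(s1$DV, s2$DV)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_pkdataset(s1, f1); write_pkdataset(s2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  s3 <- simulate_population(des, mod, seed = 100)
  expect_false(identical(s1$DV, s3$DV))
})

test_that("random-effect moments converge to the population law", {
  des <- study_design("iv_bolus", 5, sampling_times = 0.125,
                      n_subjects = 1e4, lloq = 62.5)
  mod <- population_model("iv_2cmt", iv_typical, omega = 0.3, b = 0.22)
  sim <- simulate_population(des, mod, seed = 77)
  lv <- log(attr(sim, "individual_params")[, "V"])
  se <- 0.3 / sqrt(1e4)
  expect_lt(abs(mean(lv) - log(3.60)), 3 * se)
  se_sd <- 0.3 / sqrt(2 * (1e4 - 1))
  expect_lt(abs(stats::sd(lv) - 0.3), 3 * se_sd)
})

test_that("LLOQ censoring appears at late times and grows with the limit", {
  des <- default_iv_design(n_subjects = 200)
  mod <- default_iv_model()
  sim <- simulate_population(des, mod, seed = 12)
  obs <- sim[sim$EVID == 0L, ]
  frac24 <- mean(obs$CENS[obs$TIME == 24])
  expect_gt(frac24, 0)
  expect_true(all(obs$DV[obs$CENS == 1L] == 62.5))
  des_hi <- study_design("iv_bolus", 5, des$sampling_times, 200, lloq = 200)
  obs_hi <- subset(simulate_population(des_hi, mod, seed = 12), EVID == 0L)
  expect_gt(mean(obs_hi$CENS[obs_hi$TIME == 24]), frac24)
})

test_that("mismatched route and missing seed are rejected", {
  expect_error(simulate_population(default_oral_design(), default_iv_model(),
                                   seed = 1), "route")
  expect_error(simulate_population(default_iv_design(), default_iv_model()),
               "seed")
})

test_that("tissue generator reduces to scaled plasma in the appropriate limits", {
  kp <- c(liver = 2); rate <- c(liver = Inf)
  tab <- simulate_tissue(kp, rate, noise_cv = 0, seed = 3)
  liver <- tab[tab$tissue == "liver", ]
  des <- default_tissue_design()
  ref <- conc_iv(iv_params(), dose_event(des$dose, "iv_bolus"),
                 des$sampling_times)
  expect_equal(liver$concentration,
               rep(2 * ref, each = des$n_subjects), tolerance = 1e-9)
  # zero partition coefficient: all-zero rows
  tab0 <- simulate_tissue(c(brain = 0), c(brain = 1), noise_cv = 0, seed = 3)
  expect_true(all(tab0$concentration[tab0$tissue == "brain"] == 0))
})

test_that("finite-rate tissue kinetics match a numeric convolution oracle", {
  kp <- 2; rate <- 1
  tab <- simulate_tissue(c(heart = kp), c(heart = rate), noise_cv = 0, seed = 3)
  heart <- tab[tab$tissue == "heart", ]
  m <- macro_from_micro(iv_params(), dose = 10)
  cp <- function(s) m$A_coef * exp(-m$alpha * s) + m$B_coef * exp(-m$beta * s)
  for (t in c(1, 3, 6, 11)) {
    oracle <- kp * rate * stats::integrate(function(s)
      exp(-rate * (t - s)) * cp(s), 0, t, rel.tol = 1e-10)$value
    expect_equal(unique(heart$concentration[heart$time == t]), oracle,
                 tolerance = 1e-6)
  }
  # equilibrated late ratio approaches Kp
  pl <- cp(11)
  expect_equal(unique(heart$concentration[heart$time == 11]) / pl, 2,
               tolerance = 0.05)
})

test_that("binding generator is exact without noise and calibrated with it", {
  tab <- simulate_binding(fu_true = 0.21, membrane_loss = 0.05,
                          noise_cv = 0, seed = 8)
  expect_equal((tab$unbound + tab$membrane) / tab$total, rep(0.21, nrow(tab)))
  tab1 <- simulate_binding(fu_true = 1, membrane_loss = 0, noise_cv = 0, seed = 8)
  expect_equal(tab1$unbound, tab1$total)
  # resampling oracle: CV of the fu ratio matches the generator CV
  tabn <- simulate_binding(fu_true = 0.21, membrane_loss = 0,
                           noise_cv = 0.05, totals = 1, n_rep = 1000, seed = 9)
  ratio <- tabn$unbound / tabn$total
  cv <- stats::sd(ratio) / mean(ratio)
  expect_equal(cv, sqrt(2) * 0.05, tolerance = 0.15)
})

test_that("calibration generator reproduces the validated response line", {
  tab <- simulate_calibration()
  expect_equal(tab$area[tab$conc == 1000], 44.285 * 1000 + 2130.9)
  flat <- simulate_calibration(slope = 0)
  expect_equal(length(unique(flat$area)), 1L)
  fit <- weighted_calibration(tab$conc, tab$area)
  expect_equal(fit$slope, 44.285, tolerance = 1e-12)
  expect_equal(fit$intercept, 2130.9, tolerance = 1e-9)
})
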
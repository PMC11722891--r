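test_that("macro constants satisfy the quadratic-root identities and match the eigenvalue oracle", {
  p <- iv_params()
  m <- macro_from_micro(p)
  expect_equal(m$alpha + m$beta, 1.63, tolerance = 1e-10)
  expect_equal(m$alpha * m$beta, 0.0442, tolerance = 1e-10)
  # independent oracle: eigenvalues of the 2x2 disposition rate matrix
  A <- matrix(c(-(p$k10 + p$k12), p$k21, p$k12, -p$k21), 2, 2, byrow = TRUE)
  ev <- sort(-eigen(A, only.values = TRUE)$values)
  expect_equal(m$beta, ev[1], tolerance = 1e-12)
  expect_equal(m$alpha, ev[2], tolerance = 1e-12)

  for (q in random_iv_params(50, seed = 11)) {
    mm <- macro_from_micro(q)
    expect_gt(mm$alpha, mm$beta)
    expect_equal(mm$alpha + mm$beta, q$k10 + q$k12 + q$k21, tolerance = 1e-10)
    expect_equal(mm$alpha * mm$beta, q$k10 * q$k21, tolerance = 1e-10)
  }
})

test_that("decoupled-compartment limit orders the roots as min/max of k10 and k21", {
  p <- micro_params_iv(V = 1, k10 = 0.5, k12 = 1e-10, k21 = 0.1)
  m <- macro_from_micro(p)
  expect_equal(m$beta, 0.1, tolerance = 1e-6)
  expect_equal(m$alpha, 0.5, tolerance = 1e-6)
})

test_that("repeated disposition root is rejected as degenerate", {
  # k10 = k21 and k12 = 0 makes the discriminant zero
  expect_error(macro_from_micro(micro_params_iv(1, 0.3, 1e-14, 0.3)),
               "degenerate")
})

test_that("i.v. bolus profile is correct at t = 0, linear in dose, and matches the ODE oracle", {
  p <- iv_params()
  d <- dose_event(5, "iv_bolus")
  expect_equal(conc_iv(p, d, 0), 1000 * 5 / 3.60)
  tt <- c(0, 0.125, 0.5, 1, 2, 4, 8, 16, 24)
  c1 <- conc_iv(p, d, tt)
  c2 <- conc_iv(p, dose_event(10, "iv_bolus"), tt)
  expect_equal(c2, 2 * c1)
  expect_equal(conc_iv(p, dose_event(1e-12, "iv_bolus"), tt),
               rep(0, length(tt)), tolerance = 1e-9)
  ode <- conc_ode(p, d, tt)
  expect_lt(max(abs(c1 - ode) / ode), 1e-6)
})

test_that("oral profile starts at zero, peaks, and matches the ODE oracle", {
  p <- oral_params()
  d <- dose_event(100, "oral")
  expect_equal(conc_oral(p, d, 0), 0)
  tt <- seq(0.05, 24, by = 0.05)
  cc <- conc_oral(p, d, tt)
  expect_gt(which.max(cc), 1)
  expect_lt(which.max(cc), length(cc))
  sub <- seq(1, length(tt), by = 10)
  ode <- conc_ode(p, d, tt[sub])
  expect_lt(max(abs(cc[sub] - ode) / ode), 1e-6)
})

test_that("analytic and ODE profiles agree for random parameter sets on both routes", {
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 16, 24)
  # relative agreement is assessed over the quantifiable range of each
  # profile (deep exponential tails fall below any integrator's absolute
  # tolerance)
  rel_dev <- function(ca, co) {
    keep <- ca > 1e-6 * max(ca)
    max(abs(ca[keep] - co[keep]) / ca[keep])
  }
  for (q in random_iv_params(20, seed = 21)) {
    d <- dose_event(5, "iv_bolus")
    ca <- conc_iv(q, d, tt)
    expect_lt(rel_dev(ca, conc_ode(q, d, tt, atol = 1e-12)), 1e-6)
    qo <- micro_params_oral(q$V, q$k10, q$k12, q$k21,
                            ka = stats::runif(1, 0.3, 6))
    do_ <- dose_event(100, "oral")
    co <- conc_oral(qo, do_, tt)
    expect_lt(rel_dev(co, conc_ode(qo, do_, tt, atol = 1e-12)), 1e-6)
  }
})

test_that("instantaneous-absorption limit of the oral model reproduces the i.v. profile", {
  p <- iv_params()
  po <- micro_params_oral(p$V, p$k10, p$k12, p$k21, ka = 1e6)
  tt <- seq(0.1, 24, by = 0.1)
  civ <- conc_iv(p, dose_event(5, "iv_bolus"), tt)
  cor_ <- conc_oral(po, dose_event(5, "oral"), tt)
  expect_lt(max(abs(cor_ - civ) / civ), 1e-3)
})

test_that("ka equal to a disposition rate is rejected", {
  p <- iv_params()
  al <- macro_from_micro(p)$alpha
  expect_error(conc_oral(micro_params_oral(p$V, p$k10, p$k12, p$k21, ka = al),
                         dose_event(5, "oral"), 1), "degenerate")
})

test_that("ODE right-hand side conserves mass and eliminates the full dose", {
  p <- oral_params()
  expect_equal(ode_rhs(0, c(0, 0, 0, 0), p, "oral")[[1]],
               c(depot = 0, central = 0, peripheral = 0, eliminated = 0))
  rhs <- ode_rhs(0, c(0, 5, 0, 0), p, "iv_bolus")[[1]]
  expect_equal(rhs[["peripheral"]], p$k12 * 5)
  expect_gt(rhs[["peripheral"]], 0)
  for (state in list(c(2, 1, 0.5, 0.2), c(0, 5, 0, 0))) {
    expect_equal(sum(ode_rhs(0, state, p, "oral")[[1]]), 0, tolerance = 1e-12)
  }
  # total eliminated amount converges to the dose
  out <- deSolve::ode(y = c(100, 0, 0, 0), times = c(0, 500),
                      func = function(t, y, parms) ode_rhs(t, y, p, "oral"),
                      parms = NULL, atol = 1e-10, rtol = 1e-10)
  expect_equal(unname(out[2, 5]), 100, tolerance = 1e-3)
})

test_that("secondary parameters match the closed forms and a quadrature oracle", {
  p <- iv_params()
  s <- secondary_params(p, dose = 5)
  expect_equal(s$cl, 3.60 * 0.17)
  expect_equal(s$lambda_z, macro_from_micro(p)$beta)
  expect_equal(s$t_half_terminal * s$lambda_z, log(2))
  # model-predicted AUC(0-Inf) vs dense trapezoidal quadrature to 2000 h
  tt <- c(seq(0, 50, by = 0.01), seq(50.5, 2000, by = 0.5))
  cc <- conc_iv(p, dose_event(5, "iv_bolus"), tt)
  auc_num <- sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
  expect_equal(auc_num, s$auc_inf_pred, tolerance = 5e-3)
  # one-compartment limit: terminal rate collapses to k10
  s1 <- secondary_params(micro_params_iv(2, 0.1, 1e-12, 0.5))
  expect_equal(s1$lambda_z, 0.1, tolerance = 1e-6)
})

test_that("oral and i.v. AUC coincide at equal dose and shared apparent volume", {
  p <- iv_params()
  po <- micro_params_oral(p$V, p$k10, p$k12, p$k21, ka = 1.88)
  expect_equal(secondary_params(po, dose = 5)$auc_inf_pred,
               secondary_params(p, dose = 5)$auc_inf_pred)
})

test_that("parameter and dose validation rejects bad input", {
  expect_error(micro_params_iv(-1, 0.1, 0.1, 0.1), "positive")
  expect_error(micro_params_oral(1, 0.1, 0.1, 0.1, ka = 0), "positive")
  expect_error(dose_event(0, "iv_bolus"), "positive")
  expect_error(conc_iv(iv_params(), dose_event(5, "iv_bolus"), numeric(0)),
               "non-empty")
  expect_error(conc_iv(iv_params(), dose_event(5, "iv_bolus", time = 1), 0.5),
               "dose time")
})
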
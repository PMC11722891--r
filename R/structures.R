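#' Structural model registry
#'
#' A `pk_structure` bundles a structural model's parameter names, route and
#' a vectorized predictor used by the simulator, the SAEM fitter and the
#' diagnostics. Four structures are available:
#'
#' * `iv_2cmt` — two-compartment i.v. bolus (`V, k10, k12, k21`)
#' * `oral_2cmt` — two-compartment, first-order absorption
#'   (`V, k10, k12, k21, ka`; `V` is apparent V/F)
#' * `iv_1cmt` — one-compartment i.v. bolus (`V, k10`)
#' * `oral_1cmt` — one-compartment, first-order absorption (`V, k10, ka`)
#'
#' @param name one of `"iv_2cmt"`, `"oral_2cmt"`, `"iv_1cmt"`, `"oral_1cmt"`.
#' @return A list of class `pk_structure` with elements `name`, `params`,
#'   `route`, `npar` and `predict`. The predictor has signature
#'   `(theta, dose, idx, times)` where `theta` is an `n x npar` matrix of
#'   individual parameters on the natural scale (columns in `params` order),
#'   `dose` a length-`n` vector of amounts (mg/kg), and `idx`/`times`
#'   parallel long-format vectors of subject indices and post-dose times;
#'   it returns concentrations (ng/mL) per long row.
#' @export
pk_structure <- function(name) {
  if (inherits(name, "pk_structure")) return(name)
  def <- switch(name,
    iv_2cmt   = list(params = c("V", "k10", "k12", "k21"), route = "iv_bolus",
                     predict = .predict_iv_2cmt),
    oral_2cmt = list(params = c("V", "k10", "k12", "k21", "ka"), route = "oral",
                     predict = .predict_oral_2cmt),
    iv_1cmt   = list(params = c("V", "k10"), route = "iv_bolus",
                     predict = .predict_iv_1cmt),
    oral_1cmt = list(params = c("V", "k10", "ka"), route = "oral",
                     predict = .predict_oral_1cmt),
    stop("unknown structural model: ", name, call. = FALSE))
  structure(c(list(name = name), def, list(npar = length(def$params))),
            class = "pk_structure")
}

# keep denominators away from zero while preserving sign (MCMC proposals can
# wander arbitrarily close to the degenerate ka == alpha/beta manifold)
.safe_den <- function(x, eps = 1e-12) sign(x) * pmax(abs(x), eps)

.disposition_roots <- function(k10, k12, k21) {
  s <- k10 + k12 + k21
  disc <- pmax(s^2 - 4 * k10 * k21, 0)
  r <- sqrt(disc)
  list(alpha = (s + r) / 2, beta = (s - r) / 2)
}

.predict_iv_2cmt <- function(theta, dose, idx, times) {
  V <- theta[, 1]; k10 <- theta[, 2]; k12 <- theta[, 3]; k21 <- theta[, 4]
  rt <- .disposition_roots(k10, k12, k21)
  c0 <- 1000 * dose / V
  den <- .safe_den(rt$alpha - rt$beta)
  A <- c0 * (rt$alpha - k21) / den
  B <- c0 * (k21 - rt$beta) / den
  A[idx] * exp(-rt$alpha[idx] * times) + B[idx] * exp(-rt$beta[idx] * times)
}

.predict_oral_2cmt <- function(theta, dose, idx, times) {
  V <- theta[, 1]; k10 <- theta[, 2]; k12 <- theta[, 3]; k21 <- theta[, 4]
  ka <- theta[, 5]
  rt <- .disposition_roots(k10, k12, k21)
  al <- rt$alpha; be <- rt$beta
  c0 <- 1000 * dose / V * ka
  cA <- c0 * (k21 - al) / .safe_den((ka - al) * (be - al))
  cB <- c0 * (k21 - be) / .safe_den((ka - be) * (al - be))
  cK <- c0 * (k21 - ka) / .safe_den((al - ka) * (be - ka))
  cA[idx] * exp(-al[idx] * times) + cB[idx] * exp(-be[idx] * times) +
    cK[idx] * exp(-ka[idx] * times)
}

.predict_iv_1cmt <- function(theta, dose, idx, times) {
  V <- theta[, 1]; k10 <- theta[, 2]
  c0 <- 1000 * dose / V
  c0[idx] * exp(-k10[idx] * times)
}

.predict_oral_1cmt <- function(theta, dose, idx, times) {
  V <- theta[, 1]; k10 <- theta[, 2]; ka <- theta[, 3]
  c0 <- 1000 * dose / V * ka / .safe_den(ka - k10)
  c0[idx] * (exp(-k10[idx] * times) - exp(-ka[idx] * times))
}

# micro_params -> 1-row theta matrix in structure column order
.theta_row <- function(p, structure) {
  matrix(unlist(p[structure$params]), nrow = 1,
         dimnames = list(NULL, structure$params))
}
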
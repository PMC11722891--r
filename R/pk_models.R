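#' Two-compartment micro-constant parameter sets
#'
#' Constructors for the micro-constant parameterization of the mammillary
#' two-compartment model used throughout the package. Units are fixed
#' package-wide: time in hours, volumes in L/kg, rate constants in 1/h,
#' doses in mg/kg, concentrations in ng/mL.
#'
#' For the oral model `V` is the apparent central volume `V/F`: absolute
#' bioavailability is not identifiable from a single-route fit and is
#' absorbed into the volume (and clearance) terms.
#'
#' @param V central volume of distribution (L/kg; apparent V/F for oral).
#' @param k10 first-order elimination rate constant from the central
#'   compartment (1/h).
#' @param k12,k21 first-order distribution (central to peripheral) and
#'   redistribution (peripheral to central) rate constants (1/h).
#' @param ka first-order absorption rate constant (1/h, oral only).
#' @return An object of class `micro_params_iv` or `micro_params_oral`
#'   (named list of the rates).
#' @examples
#' p <- micro_params_iv(V = 3.60, k10 = 0.17, k12 = 1.20, k21 = 0.26)
#' macro_from_micro(p)
#' @export
micro_params_iv <- function(V, k10, k12, k21) {
  p <- list(V = V, k10 = k10, k12 = k12, k21 = k21)
  .check_positive(p)
  structure(p, class = c("micro_params_iv", "micro_params"))
}

#' @rdname micro_params_iv
#' @export
micro_params_oral <- function(V, k10, k12, k21, ka) {
  p <- list(V = V, k10 = k10, k12 = k12, k21 = k21, ka = ka)
  .check_positive(p)
  structure(p, class = c("micro_params_oral", "micro_params"))
}

.check_positive <- function(p) {
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad))
    stop("pharmacokinetic parameters must be finite, strictly positive scalars: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  invisible(p)
}

#' Dosing event
#'
#' @param amount dose amount (mg/kg), strictly positive.
#' @param route `"iv_bolus"` or `"oral"`.
#' @param time dosing time (h, non-negative; defaults to 0).
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(amount, route = c("iv_bolus", "oral"), time = 0) {
  route <- match.arg(route)
  if (!is.numeric(amount) || length(amount) != 1L || !is.finite(amount) || amount <= 0)
    stop("dose amount must be a positive finite scalar (mg/kg)", call. = FALSE)
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) || time < 0)
    stop("dose time must be a non-negative finite scalar (h)", call. = FALSE)
  structure(list(amount = amount, route = route, time = time), class = "dose_event")
}

#' Macro (biexponential) disposition constants from micro constants
#'
#' Converts the micro-constant parameterization into the macro disposition
#' rates `alpha > beta`, the two roots of
#' `lambda^2 - (k10 + k12 + k21) lambda + k10 k21 = 0`,
#' together with the i.v. bolus intercept coefficients for a given dose.
#'
#' @param p a `micro_params_iv` (or oral) parameter set.
#' @param dose optional dose amount (mg/kg) used to scale the intercepts
#'   `A_coef`, `B_coef` (ng/mL); if omitted the intercepts are per unit dose.
#' @return A list of class `macro_params` with elements `alpha`, `beta`
#'   (1/h) and `A_coef`, `B_coef` (ng/mL).
#' @details The roots satisfy `alpha + beta = k10 + k12 + k21` and
#'   `alpha * beta = k10 * k21` (checked identities). A numerically repeated
#'   root (discriminant <= 0) is rejected as a degenerate model rather than
#'   handled by a limit form.
#' @export
macro_from_micro <- function(p, dose = 1) {
  stopifnot(inherits(p, "micro_params"))
  s <- p$k10 + p$k12 + p$k21
  pr <- p$k10 * p$k21
  disc <- s^2 - 4 * pr
  if (disc <= max(1e-12 * s^2, 0))
    stop("degenerate two-compartment model: repeated disposition root ",
         "(discriminant <= 0)", call. = FALSE)
  r <- sqrt(disc)
  alpha <- (s + r) / 2
  beta <- (s - r) / 2
  c0 <- 1000 * dose / p$V  # mg/kg over L/kg -> mg/L, x1000 -> ng/mL
  structure(list(alpha = alpha, beta = beta,
                 A_coef = c0 * (alpha - p$k21) / (alpha - beta),
                 B_coef = c0 * (p$k21 - beta) / (alpha - beta)),
            class = "macro_params")
}

#' Analytic concentration-time profiles
#'
#' Closed-form plasma concentrations for the two-compartment model:
#' biexponential decay after an i.v. bolus, triexponential
#' (absorption + two disposition phases) after an oral dose with
#' first-order absorption.
#'
#' @param p `micro_params_iv` for `conc_iv`, `micro_params_oral` for
#'   `conc_oral`.
#' @param dose a [dose_event()] whose route matches the model.
#' @param times numeric vector of sampling times (h), all `>= dose$time`.
#' @return numeric vector of concentrations (ng/mL).
#' @details The oral solution divides by `(ka - alpha)` and `(ka - beta)`;
#'   an absorption rate within 1e-8 relative of either disposition rate is
#'   rejected as degenerate rather than switched to the repeated-root form.
#' @examples
#' p <- micro_params_iv(V = 3.60, k10 = 0.17, k12 = 1.20, k21 = 0.26)
#' conc_iv(p, dose_event(5, "iv_bolus"), times = c(0, 0.5, 2, 8, 24))
#' @export
conc_iv <- function(p, dose, times) {
  stopifnot(inherits(p, "micro_params_iv"), inherits(dose, "dose_event"))
  if (dose$route != "iv_bolus") stop("conc_iv requires an iv_bolus dose", call. = FALSE)
  .check_times(times, dose$time)
  m <- macro_from_micro(p, dose = dose$amount)
  tau <- times - dose$time
  m$A_coef * exp(-m$alpha * tau) + m$B_coef * exp(-m$beta * tau)
}

#' @rdname conc_iv
#' @export
conc_oral <- function(p, dose, times) {
  stopifnot(inherits(p, "micro_params_oral"), inherits(dose, "dose_event"))
  if (dose$route != "oral") stop("conc_oral requires an oral dose", call. = FALSE)
  .check_times(times, dose$time)
  m <- macro_from_micro(p, dose = dose$amount)
  if (abs(p$ka - m$alpha) <= 1e-8 * m$alpha ||
      abs(p$ka - m$beta) <= 1e-8 * m$beta)
    stop("degenerate oral model: ka coincides with a disposition rate",
         call. = FALSE)
  tau <- times - dose$time
  c0 <- 1000 * dose$amount / p$V
  ka <- p$ka; al <- m$alpha; be <- m$beta; k21 <- p$k21
  c0 * ka * ((k21 - al) / ((ka - al) * (be - al)) * exp(-al * tau) +
             (k21 - be) / ((ka - be) * (al - be)) * exp(-be * tau) +
             (k21 - ka) / ((al - ka) * (be - ka)) * exp(-ka * tau))
}

.check_times <- function(times, t0) {
  if (!is.numeric(times) || length(times) == 0L)
    stop("times must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(times)) || any(times < t0))
    stop("all sampling times must be finite and >= the dose time", call. = FALSE)
  invisible(times)
}

#' Right-hand side of the amount-space compartment ODE system
#'
#' Mass-balanced amount-space system for the two-compartment model with an
#' elimination bookkeeping compartment, in the signature expected by
#' [deSolve::ode()]. State is `c(depot, central, peripheral, eliminated)`
#' (depot ignored for i.v.); amounts in mg/kg.
#'
#' \deqn{dA_0/dt = -k_a A_0 \quad (oral)}
#' \deqn{dA_1/dt = k_a A_0 - (k_{10} + k_{12}) A_1 + k_{21} A_2}
#' \deqn{dA_2/dt = k_{12} A_1 - k_{21} A_2}
#' \deqn{dA_e/dt = k_{10} A_1}
#'
#' The system conserves total mass: the four derivatives sum to zero.
#'
#' @param t time (h; unused, the system is autonomous).
#' @param state named or positional numeric vector
#'   `c(depot, central, peripheral, eliminated)`.
#' @param p a `micro_params` object.
#' @param route `"iv_bolus"` or `"oral"`.
#' @return A list whose first element is the derivative vector
#'   (deSolve convention).
#' @export
ode_rhs <- function(t, state, p, route = c("iv_bolus", "oral")) {
  route <- match.arg(route)
  a0 <- state[[1]]; a1 <- state[[2]]; a2 <- state[[3]]
  dabs <- if (route == "oral") p$ka * a0 else 0
  list(c(
    depot = -dabs,
    central = dabs - (p$k10 + p$k12) * a1 + p$k21 * a2,
    peripheral = p$k12 * a1 - p$k21 * a2,
    eliminated = p$k10 * a1
  ))
}

#' Numerically integrated concentration profile
#'
#' Integrates [ode_rhs()] with `deSolve::lsoda` and converts the central
#' amount to a concentration (`C = 1000 A1 / V`, ng/mL). This is the
#' reference route against which the closed-form solutions are checked.
#'
#' @inheritParams conc_iv
#' @param atol,rtol integrator tolerances.
#' @return numeric vector of concentrations (ng/mL) at `times`.
#' @export
conc_ode <- function(p, dose, times, atol = 1e-10, rtol = 1e-10) {
  stopifnot(inherits(p, "micro_params"), inherits(dose, "dose_event"))
  .check_times(times, dose$time)
  y0 <- if (dose$route == "oral") c(dose$amount, 0, 0, 0) else c(0, dose$amount, 0, 0)
  tt <- sort(unique(c(dose$time, times)))
  out <- deSolve::ode(y = y0, times = tt,
                      func = function(t, y, parms) ode_rhs(t, y, p, dose$route),
                      parms = NULL, atol = atol, rtol = rtol)
  central <- out[match(times, out[, 1]), 3]
  1000 * central / p$V
}

#' Secondary (derived) pharmacokinetic parameters
#'
#' Model-implied exposure parameters: terminal rate `lambda_z` (the slow
#' disposition root `beta`), terminal half-life, clearance `CL = V * k10`
#' and, when a dose is supplied, the model-predicted
#' `AUC(0-Inf) = 1000 * dose / (V * k10)` (ng*h/mL). For the oral model
#' these are apparent quantities (CL/F, V/F).
#'
#' @param p a `micro_params` object.
#' @param dose optional dose amount (mg/kg).
#' @return list with `lambda_z` (1/h), `t_half_terminal` (h), `cl`
#'   (L/h/kg) and `auc_inf_pred` (ng*h/mL, `NA` without a dose).
#' @export
secondary_params <- function(p, dose = NULL) {
  stopifnot(inherits(p, "micro_params"))
  m <- macro_from_micro(p)
  list(lambda_z = m$beta,
       t_half_terminal = log(2) / m$beta,
       cl = p$V * p$k10,
       auc_inf_pred = if (is.null(dose)) NA_real_ else 1000 * dose / (p$V * p$k10))
}
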
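#' Terminal slope (lambda_z) estimation
#'
#' Log-linear least-squares on the terminal portion of a concentration-time
#' profile. The terminal subset is chosen by maximizing the adjusted R^2
#' over all suffixes of at least three points (the de-facto standard rule);
#' for oral profiles the observation at Cmax is excluded from candidacy.
#' Ties within 1e-4 prefer the longer suffix.
#'
#' @param time,conc numeric vectors (h, ng/mL); censored values must already
#'   be removed. All `conc` must be positive to enter the log fit.
#' @param exclude_cmax drop the Cmax point and everything before it from the
#'   candidate tail (use for extravascular profiles).
#' @return list with `lambda_z` (1/h), `r2_adj`, `n_points`, `intercept`
#'   (log ng/mL) and logical `flag_poor_fit` (`r2_adj < 0.5`).
#' @export
fit_lambda_z <- function(time, conc, exclude_cmax = FALSE) {
  stopifnot(length(time) == length(conc))
  keep <- is.finite(time) & is.finite(conc) & conc > 0
  time <- time[keep]; conc <- conc[keep]
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  if (exclude_cmax) {
    i_max <- which.max(conc)
    time <- time[-seq_len(i_max)]
    conc <- conc[-seq_len(i_max)]
  }
  n <- length(time)
  if (n < 3L)
    stop("no terminal phase: fewer than 3 usable post-peak observations",
         call. = FALSE)
  lc <- log(conc)
  cand <- list()
  for (k in 3:n) {
    idx <- (n - k + 1):n
    if (stats::var(lc[idx]) == 0) next  # flat tail, no decline
    fit <- stats::lm.fit(cbind(1, time[idx]), lc[idx])
    slope <- fit$coefficients[2]
    if (slope >= 0) next  # not declining over this suffix
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((lc[idx] - mean(lc[idx]))^2)
    r2 <- 1 - ss_res / ss_tot
    r2_adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    cand[[length(cand) + 1L]] <-
      list(lambda_z = unname(-slope), r2_adj = r2_adj, n_points = k,
           intercept = unname(fit$coefficients[1]))
  }
  if (length(cand) == 0L)
    stop("no terminal phase: tail shows no log-linear decline", call. = FALSE)
  r2s <- vapply(cand, `[[`, numeric(1), "r2_adj")
  ok <- which(r2s >= max(r2s) - 1e-4)
  best <- cand[[ok[length(ok)]]]  # longest suffix among near-ties
  best$flag_poor_fit <- best$r2_adj < 0.5
  best
}

#' Trapezoidal AUC and AUMC
#'
#' Area under the concentration-time curve and under the first-moment curve
#' by the trapezoidal rule. The default `linear_up_log_down` method uses the
#' linear trapezoid on non-decreasing segments and the log trapezoid
#' `(C1 - C2) / ln(C1/C2) * dt` on declining segments with both endpoints
#' positive; `linear` uses the linear rule throughout. AUMC uses the
#' matching moment formulas (exact for exponential interpolation on log
#' segments).
#'
#' @param time,conc numeric vectors, time strictly increasing.
#' @param method `"linear_up_log_down"` (default) or `"linear"`.
#' @return list with `auc` (ng*h/mL) and `aumc` (ng*h^2/mL) from the first
#'   to the last observation.
#' @export
auc_trapezoid <- function(time, conc, method = c("linear_up_log_down", "linear")) {
  method <- match.arg(method)
  stopifnot(length(time) == length(conc), length(time) >= 2L)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  t1 <- time[-length(time)]; t2 <- time[-1]
  c1 <- conc[-length(conc)]; c2 <- conc[-1]
  dt <- t2 - t1
  auc_lin <- dt * (c1 + c2) / 2
  aumc_lin <- dt * (t1 * c1 + t2 * c2) / 2
  use_log <- method == "linear_up_log_down" & c2 < c1 & c2 > 0 & c1 > 0
  auc <- auc_lin; aumc <- aumc_lin
  if (any(use_log)) {
    lam <- log(c1[use_log] / c2[use_log]) / dt[use_log]
    auc[use_log] <- (c1[use_log] - c2[use_log]) / lam
    aumc[use_log] <- (t1[use_log] * c1[use_log] - t2[use_log] * c2[use_log]) / lam +
      (c1[use_log] - c2[use_log]) / lam^2
  }
  list(auc = sum(auc), aumc = sum(aumc))
}

#' Per-subject non-compartmental analysis
#'
#' Assembles the standard single-dose NCA parameter set from one subject's
#' profile: terminal rate constant and half-life, AUC and AUMC to the last
#' quantifiable observation and extrapolated to infinity, mean residence
#' time, clearance, terminal volume of distribution and (for oral data)
#' Cmax/Tmax by inspection. Extrapolation uses the observed last
#' concentration: `AUC(0-Inf) = AUC(0-t) + Clast / lambda_z`.
#'
#' For oral data CL and Vd are apparent (CL/F, Vz/F) and MRT is reported
#' as-is, without absorption-time correction.
#'
#' @param time,conc observed profile (censored records removed beforehand or
#'   via [nca_dataset()]).
#' @param dose dose amount (mg/kg).
#' @param route `"iv_bolus"` or `"oral"`.
#' @param method trapezoid method passed to [auc_trapezoid()].
#' @return object of class `nca_result`: list with fields `lambda_z`,
#'   `t_half`, `auc_0_t`, `auc_0_inf`, `aumc_0_inf`, `mrt`, `cl`, `vd`,
#'   `cmax`, `tmax`, `n_terminal_points`, `r2_adj`.
#' @export
nca_summary <- function(time, conc, dose, route = c("iv_bolus", "oral"),
                        method = "linear_up_log_down") {
  route <- match.arg(route)
  keep <- is.finite(time) & is.finite(conc) & conc > 0
  time <- time[keep]; conc <- conc[keep]
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  if (length(time) < 3L) stop("too few quantifiable observations for NCA",
                              call. = FALSE)
  lz <- fit_lambda_z(time, conc, exclude_cmax = route == "oral")
  tr <- auc_trapezoid(time, conc, method = method)
  # leading area from dose time (0) to the first sample
  c_first <- conc[1]; t_first <- time[1]
  if (route == "iv_bolus") {
    # back-extrapolate C(0) from the first two samples (log-linear)
    c0 <- if (length(conc) >= 2L && conc[2] < conc[1] && conc[2] > 0)
      exp(log(c_first) + (log(c_first) - log(conc[2])) /
            (time[2] - t_first) * t_first)
    else c_first
    auc_lead <- t_first * (c0 + c_first) / 2
    aumc_lead <- t_first * (t_first * c_first) / 2
  } else {
    auc_lead <- t_first * c_first / 2   # linear rise from C(0) = 0
    aumc_lead <- t_first * (t_first * c_first) / 2
  }
  c_last <- conc[length(conc)]; t_last <- time[length(time)]
  auc_0_t <- auc_lead + tr$auc
  auc_inf <- auc_0_t + c_last / lz$lambda_z
  aumc_inf <- aumc_lead + tr$aumc + c_last * t_last / lz$lambda_z +
    c_last / lz$lambda_z^2
  cl <- 1000 * dose / auc_inf
  structure(list(lambda_z = lz$lambda_z,
                 t_half = log(2) / lz$lambda_z,
                 auc_0_t = auc_0_t,
                 auc_0_inf = auc_inf,
                 aumc_0_inf = aumc_inf,
                 mrt = aumc_inf / auc_inf,
                 cl = cl,
                 vd = cl / lz$lambda_z,
                 cmax = max(conc),
                 tmax = time[which.max(conc)],
                 n_terminal_points = lz$n_points,
                 r2_adj = lz$r2_adj),
            class = "nca_result")
}

#' NCA over a population dataset
#'
#' Runs [nca_summary()] on every subject of a `pk_dataset` (censored
#' observations are dropped; a censored record ending the profile simply
#' truncates AUC(0-t) at the last quantifiable sample) and returns the
#' per-subject parameter table with mean and SD rows attached as an
#' attribute.
#'
#' @param data a `pk_dataset` (see [simulate_population()] /
#'   [read_pkdataset()]).
#' @param method trapezoid method.
#' @return data.frame, one row per subject, columns the `nca_result`
#'   fields plus `ID`; attribute `"summary"` holds mean/SD across subjects.
#' @export
nca_dataset <- function(data, method = "linear_up_log_down") {
  stopifnot(is.data.frame(data))
  ids <- unique(data$ID)
  rows <- lapply(ids, function(id) {
    sub <- data[data$ID == id, ]
    dose_row <- sub[sub$EVID == 1L, ]
    if (nrow(dose_row) != 1L)
      stop("subject ", id, " must have exactly one dose record", call. = FALSE)
    obs <- sub[sub$EVID == 0L & sub$CENS == 0L, ]
    res <- nca_summary(obs$TIME, obs$DV, dose = dose_row$AMT,
                       route = dose_row$ROUTE, method = method)
    cbind(data.frame(ID = id), as.data.frame(unclass(res)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  num <- out[, setdiff(names(out), "ID")]
  attr(out, "summary") <- data.frame(stat = c("mean", "sd"),
                                     rbind(colMeans(num), apply(num, 2, stats::sd)))
  out
}

#' Absolute oral bioavailability
#'
#' Dose-normalized AUC ratio of the oral to the intravenous route:
#' `F = (AUC_oral / dose_oral) / (AUC_iv / dose_iv)`. Any consistent AUC
#' unit may be used as long as both routes share it.
#'
#' @param auc_oral,auc_iv AUC(0-Inf) for each route (ng*h/mL).
#' @param dose_oral,dose_iv dose amounts (mg/kg).
#' @return bioavailability as a fraction.
#' @examples
#' bioavailability(6519, 100, 6076, 5)  # ~0.054
#' @export
bioavailability <- function(auc_oral, dose_oral, auc_iv, dose_iv) {
  stopifnot(auc_oral > 0, auc_iv > 0, dose_oral > 0, dose_iv > 0)
  (auc_oral / dose_oral) / (auc_iv / dose_iv)
}
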
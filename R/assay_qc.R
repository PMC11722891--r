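#' Weighted calibration regression
#'
#' Weighted least-squares fit of detector response on nominal concentration
#' with weights 1, 1/x or 1/x^2 (heteroscedastic chromatographic responses
#' are conventionally fitted with inverse-concentration weighting). Each
#' standard is back-calculated through the inverted line and its accuracy
#' checked against the acceptance window (85-115%, relaxed to 80-120% at
#' the LLOQ).
#'
#' @param conc,area calibration standards: nominal concentrations (ng/mL)
#'   and peak areas.
#' @param weighting `"inverse_conc"` (default, w = 1/x), `"none"` or
#'   `"inverse_conc_sq"` (w = 1/x^2).
#' @param lloq lowest standard treated as the LLOQ for the acceptance
#'   window (defaults to the smallest nominal concentration).
#' @return object of class `calibration_fit`: list with `slope`,
#'   `intercept`, `r2` (weighted), `weighting`, `back_calc` (data.frame
#'   with `conc`, `area`, `back_conc`, `accuracy_pct`, `pass`).
#' @export
weighted_calibration <- function(conc, area,
                                 weighting = c("inverse_conc", "none",
                                               "inverse_conc_sq"),
                                 lloq = min(conc)) {
  weighting <- match.arg(weighting)
  stopifnot(length(conc) == length(area), length(conc) >= 2, all(conc > 0))
  w <- switch(weighting, none = rep(1, length(conc)),
              inverse_conc = 1 / conc, inverse_conc_sq = 1 / conc^2)
  fit <- stats::lm(area ~ conc, weights = w)
  cf <- stats::coef(fit)
  wmean <- sum(w * area) / sum(w)
  ss_tot <- sum(w * (area - wmean)^2)
  r2 <- if (ss_tot > 0) 1 - sum(w * stats::residuals(fit)^2) / ss_tot else 0
  back <- (area - cf[[1]]) / cf[[2]]
  acc <- 100 * back / conc
  win_lo <- ifelse(conc <= lloq, 80, 85)
  win_hi <- ifelse(conc <= lloq, 120, 115)
  structure(list(slope = cf[[2]], intercept = cf[[1]], r2 = r2,
                 weighting = weighting,
                 back_calc = data.frame(conc = conc, area = area,
                                        back_conc = back, accuracy_pct = acc,
                                        pass = acc >= win_lo & acc <= win_hi)),
            class = "calibration_fit")
}

#' Precision and accuracy report for quality-control runs
#'
#' Intra-day and inter-day precision (CV%) and accuracy (% of nominal) per
#' QC level, with pass/fail flags per the usual bioanalytical acceptance
#' windows: CV <= 15% and accuracy within 85-115%, relaxed to CV <= 20%
#' and 80-120% at the LLOQ. All windows are closed intervals: boundary
#' values pass.
#'
#' @param qc data.frame with columns `level` (nominal concentration,
#'   ng/mL), `day` (integer), `measured` (ng/mL); replicate order is
#'   irrelevant.
#' @param lloq LLOQ (ng/mL); levels `<= lloq` get the relaxed windows.
#' @return object of class `qc_report`: data.frame with one row per level:
#'   `level`, `n`, `intra_day_cv_pct` (mean of within-day CVs),
#'   `inter_day_cv_pct` (CV of day means), `accuracy_pct`, `cv_pass`,
#'   `accuracy_pass`.
#' @export
qc_report <- function(qc, lloq = 62.5) {
  stopifnot(all(c("level", "day", "measured") %in% names(qc)))
  levels_ <- sort(unique(qc$level))
  rows <- lapply(levels_, function(lv) {
    x <- qc[qc$level == lv, ]
    by_day <- split(x$measured, x$day)
    cv <- function(v) if (length(v) >= 2) 100 * stats::sd(v) / mean(v) else NA_real_
    intra <- mean(vapply(by_day, cv, numeric(1)), na.rm = TRUE)
    day_means <- vapply(by_day, mean, numeric(1))
    inter <- if (length(day_means) >= 2) cv(day_means) else NA_real_
    acc <- 100 * mean(x$measured) / lv
    cv_lim <- if (lv <= lloq) 20 else 15
    acc_lo <- if (lv <= lloq) 80 else 85
    acc_hi <- if (lv <= lloq) 120 else 115
    worst_cv <- max(c(intra, inter), na.rm = TRUE)
    data.frame(level = lv, n = nrow(x), intra_day_cv_pct = intra,
               inter_day_cv_pct = inter, accuracy_pct = acc,
               cv_pass = worst_cv <= cv_lim,
               accuracy_pass = acc >= acc_lo & acc <= acc_hi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Long-term matrix stability check
#'
#' Stability% = 100 * stored / baseline per storage interval; samples are
#' considered stable when the result lies within 100 +/- 15% (closed
#' interval).
#'
#' @param baseline numeric vector of baseline replicate measurements.
#' @param stored named list of replicate vectors per storage interval
#'   (e.g. `list(t30 = ..., t60 = ..., t90 = ...)`).
#' @return data.frame with `interval`, `stability_pct`, `pass`.
#' @export
stability_check <- function(baseline, stored) {
  stopifnot(is.numeric(baseline), length(baseline) >= 1,
            is.list(stored), !is.null(names(stored)))
  base <- mean(baseline)
  out <- do.call(rbind, lapply(names(stored), function(nm) {
    s <- 100 * mean(stored[[nm]]) / base
    data.frame(interval = nm, stability_pct = s, pass = s >= 85 & s <= 115)
  }))
  rownames(out) <- NULL
  out
}

#' Extraction recovery
#'
#' Recovery% per level as the ratio of responses from extracted samples to
#' neat (unextracted) solutions, pooled as mean +/- SD.
#'
#' @param extracted,neat data.frames with columns `level` and `response`.
#' @return list with `per_level` (level, recovery_pct) and pooled
#'   `mean_pct`, `sd_pct`.
#' @export
recovery_summary <- function(extracted, neat) {
  stopifnot(all(c("level", "response") %in% names(extracted)),
            all(c("level", "response") %in% names(neat)))
  lev <- sort(unique(extracted$level))
  rec <- vapply(lev, function(lv) {
    100 * mean(extracted$response[extracted$level == lv]) /
      mean(neat$response[neat$level == lv])
  }, numeric(1))
  list(per_level = data.frame(level = lev, recovery_pct = rec),
       mean_pct = mean(rec), sd_pct = stats::sd(rec))
}
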
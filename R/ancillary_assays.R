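#' Fraction unbound from an ultrafiltration binding table
#'
#' Computes `fu = Cu / Ct` per replicate, pools across replicates and
#' concentrations, and assesses linearity of binding (ordinary least
#' squares of `fu` on total concentration with a zero-slope test).
#' Drug adsorbed to the ultrafiltration membrane is quantified separately
#' and can be used to adjust the estimate:
#'
#' * `"additive"` (default): the membrane-bound amount is recovered into
#'   the unbound concentration, `Cu = filtrate + membrane`.
#' * `"denominator"`: the membrane-bound amount is removed from the total,
#'   `fu = filtrate / (Ct - membrane)`.
#' * `"none"`: `fu = filtrate / Ct` uncorrected.
#'
#' Rows with corrected `Cu > Ct` (fu > 1) are flagged and excluded from the
#' pooled estimate with a warning.
#'
#' @param table a `binding_table` (see [simulate_binding()]): data.frame
#'   with columns `total`, `unbound` and (for corrections) `membrane`.
#' @param correction membrane-adjustment mode.
#' @return object of class `binding_result`: list with `per_row`
#'   (data.frame of per-replicate fu), `fu_mean`, `fu_sd`,
#'   `bound_pct` (100 * (1 - fu_mean)), `linearity` (slope, its 95% CI and
#'   zero-slope p-value), `n_flagged`.
#' @export
fraction_unbound <- function(table,
                             correction = c("additive", "none", "denominator")) {
  correction <- match.arg(correction)
  stopifnot(all(c("total", "unbound") %in% names(table)))
  if (correction != "none" && !"membrane" %in% names(table))
    stop("membrane correction requested but no 'membrane' column present",
         call. = FALSE)
  fu <- switch(correction,
    none = table$unbound / table$total,
    additive = (table$unbound + table$membrane) / table$total,
    denominator = table$unbound / (table$total - table$membrane))
  flagged <- !is.finite(fu) | fu > 1 | fu < 0
  if (any(flagged))
    warning(sum(flagged), " row(s) with corrected Cu outside [0, Ct] excluded",
            call. = FALSE)
  per_row <- data.frame(total = table$total, fu = fu, flagged = flagged)
  ok <- !flagged
  lin <- if (sum(ok) >= 3 && stats::var(table$total[ok]) > 0) {
    m <- stats::lm(fu ~ total, data = per_row[ok, ])
    sl <- unname(stats::coef(m)["total"])
    if (sum(stats::residuals(m)^2) < 1e-20 * max(mean(fu[ok])^2, 1e-20)) {
      # noiseless table: the line is exact, a significance test is moot
      list(slope = sl, ci_lo = sl, ci_hi = sl, p_value = NA_real_)
    } else {
      cf <- summary(m)$coefficients
      ci <- stats::confint(m)["total", ]
      list(slope = sl, ci_lo = ci[[1]], ci_hi = ci[[2]],
           p_value = cf["total", "Pr(>|t|)"])
    }
  } else list(slope = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
              p_value = NA_real_)
  structure(list(per_row = per_row,
                 fu_mean = mean(fu[ok]), fu_sd = stats::sd(fu[ok]),
                 bound_pct = 100 * (1 - mean(fu[ok])),
                 linearity = lin, n_flagged = sum(flagged),
                 correction = correction),
            class = "binding_result")
}

#' Tissue distribution summary
#'
#' Groupwise mean, SD and n per tissue and time, plus the apparent
#' tissue-to-plasma partition coefficient `Kp,app` (ratio of tissue mean to
#' plasma mean at the matched time) where plasma rows are present. With a
#' destructive terminal-sampling design there is no per-animal pairing
#' across times, so `Kp,app` uses group means. Missing plasma at a time
#' yields `NA` (absent), never zero.
#'
#' @param table a `tissue_table` (see [simulate_tissue()]): data.frame with
#'   columns `tissue`, `time`, `replicate`, `concentration`.
#' @return data.frame (`tissue_summary`) with columns `tissue`, `time`,
#'   `mean`, `sd`, `n`, `kp_app`.
#' @export
tissue_summary <- function(table) {
  stopifnot(all(c("tissue", "time", "concentration") %in% names(table)))
  agg <- stats::aggregate(concentration ~ tissue + time, data = table,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(tissue = agg$tissue, time = agg$time,
                    mean = agg$concentration[, "mean"],
                    sd = agg$concentration[, "sd"],
                    n = as.integer(agg$concentration[, "n"]))
  plasma <- out[out$tissue == "plasma", ]
  out$kp_app <- if (nrow(plasma)) {
    pm <- plasma$mean[match(out$time, plasma$time)]
    ifelse(out$tissue == "plasma", 1, out$mean / pm)
  } else NA_real_
  out <- out[order(out$tissue, out$time), ]
  rownames(out) <- NULL
  class(out) <- c("tissue_summary", "data.frame")
  out
}
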
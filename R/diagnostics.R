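#' Wrap a known population model as a fit object
#'
#' Builds a `saem_fit`-shaped object directly from a [population_model()]
#' and a dataset, without estimation. Useful for diagnostics calibration
#' (running VPC/NPDE under the data-generating model) and for computing
#' predictions at externally supplied parameter values. Empirical Bayes
#' estimates are computed by per-subject conditional-mode optimization.
#'
#' @param model a [population_model()].
#' @param data a `pk_dataset` whose route matches the model.
#' @param blq below-LLOQ policy, as in [fit_settings()].
#' @return object of class `saem_fit` (without likelihood/RSE fields).
#' @export
population_fit <- function(model, data, blq = "drop") {
  stopifnot(inherits(model, "population_model"))
  structure_ <- model$structure
  sd_ <- .saem_data(data, structure_, blq = blq)
  p <- structure_$npar
  mu <- log(model$typical)
  omega2 <- pmax(model$omega^2, 1e-10)
  start <- matrix(unname(mu), sd_$n, p, byrow = TRUE)
  phi_map <- .ebe_modes(start, unname(mu), unname(omega2), model$b, sd_,
                        structure_)
  ebe <- sweep(phi_map, 2, unname(mu))
  colnames(ebe) <- structure_$params
  # linearized conditional covariance (G' R^-1 G + Omega^-1)^-1 per subject,
  # used as the importance-sampling proposal
  post_cov <- lapply(seq_len(sd_$n), function(i) {
    rows <- sd_$idx == i
    ti <- sd_$times[rows]
    f <- structure_$predict(matrix(exp(phi_map[i, ]), 1), sd_$dose[i],
                            rep(1L, sum(rows)), ti)
    G <- .sens_matrix(phi_map[i, ], sd_$dose[i], ti, structure_)
    prec <- crossprod(G / (model$b * f)) + diag(1 / unname(omega2), p)
    cc <- try(solve(prec), silent = TRUE)
    if (inherits(cc, "try-error") || any(!is.finite(cc)))
      diag(unname(omega2), p) else (cc + t(cc)) / 2
  })
  structure(list(theta_hat = model$typical, omega_hat = model$omega,
                 b_hat = model$b, n_par = 2L * p + 1L,
                 ebe = ebe, phi_map = phi_map,
                 post_cov = post_cov,
                 converged = NA, structure = structure_, data = data,
                 saem_data = sd_),
            class = "saem_fit")
}

# simulate n_sim replicate observation matrices under the population model
# at the observed design; returns list(sim = n_sim x n_obs matrix, ...)
.simulate_replicates <- function(fit, n_sim, seed) {
  sd_ <- fit$saem_data
  structure <- fit$structure
  p <- structure$npar
  set.seed(as.integer(seed))
  mu <- log(fit$theta_hat)
  omega <- fit$omega_hat
  sim <- matrix(NA_real_, n_sim, sd_$n_obs)
  for (r in seq_len(n_sim)) {
    eta <- matrix(stats::rnorm(sd_$n * p), sd_$n, p) %*% diag(omega, p)
    theta_i <- exp(sweep(eta, 2, unname(mu), "+"))
    f <- structure$predict(theta_i, sd_$dose, sd_$idx, sd_$times)
    sim[r, ] <- f * (1 + stats::rnorm(sd_$n_obs, 0, fit$b_hat))
  }
  sim
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the fitted model at the
#' observed design, and compares the observed 5th/50th/95th concentration
#' percentiles per time bin with the simulation-based 90% confidence band
#' of each percentile. Designs here use nominal sampling times, so binning
#' defaults to one bin per nominal time.
#'
#' @param fit a [saem_fit()] or [population_fit()] object.
#' @param n_sim number of simulated replicates (default 1000).
#' @param seed integer seed; the result is a pure function of
#'   (fit, seed, n_sim).
#' @param bins optional numeric vector of bin edges; observations are
#'   assigned to the enclosing interval. Default: one bin per unique time.
#' @param probs percentiles to check.
#' @return object of class `vpc_result`: data.frame with columns `bin`
#'   (representative time), `percentile`, `observed`, `band_lo`, `band_med`,
#'   `band_hi`; attributes `n_sim` and `seed`.
#' @export
vpc <- function(fit, n_sim = 1000, seed = 1, bins = NULL,
                probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(fit, "saem_fit"))
  sd_ <- fit$saem_data
  sim <- .simulate_replicates(fit, n_sim, seed)
  grp <- if (is.null(bins)) factor(sd_$times) else
    cut(sd_$times, breaks = bins, include.lowest = TRUE)
  bin_time <- tapply(sd_$times, grp, stats::median)
  rows <- list()
  for (g in levels(grp)) {
    cols <- which(grp == g)
    obs_q <- stats::quantile(sd_$y[cols], probs, names = FALSE)
    sim_q <- t(apply(sim[, cols, drop = FALSE], 1, stats::quantile,
                     probs = probs, names = FALSE))
    band <- apply(sim_q, 2, stats::quantile, probs = c(0.05, 0.5, 0.95),
                  names = FALSE)
    rows[[g]] <- data.frame(bin = bin_time[[g]], percentile = 100 * probs,
                            observed = obs_q, band_lo = band[1, ],
                            band_med = band[2, ], band_hi = band[3, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  class(out) <- c("vpc_result", "data.frame")
  out
}

#' Normalized prediction distribution errors
#'
#' For each subject, simulates `n_sim` prediction vectors under the fitted
#' population model, decorrelates the observed vector with the simulated
#' mean and the Cholesky factor of the simulated covariance (ridge 1e-8),
#' and maps the componentwise ranks of the decorrelated observations among
#' the equally decorrelated simulations through the standard normal
#' quantile. Under a correct model the NPDE are approximately iid N(0, 1):
#' their mean and variance should be close to 0 and 1.
#'
#' @param fit a [saem_fit()] or [population_fit()] object.
#' @param n_sim simulated replicates (default 1000).
#' @param seed integer seed.
#' @return object of class `npde_result`: list with `npde` (one value per
#'   uncensored observation, in dataset order), `mean`, `variance`,
#'   `p_mean` (t test of mean 0), `p_var` (chi-square test of unit
#'   variance), `p_normal` (Shapiro-Wilk), `p_ks`
#'   (Kolmogorov-Smirnov vs N(0,1)), `n_sim`, `seed`.
#' @export
npde <- function(fit, n_sim = 1000, seed = 1) {
  stopifnot(inherits(fit, "saem_fit"))
  sd_ <- fit$saem_data
  sim <- .simulate_replicates(fit, n_sim, seed)
  npde_all <- numeric(sd_$n_obs)
  for (i in seq_len(sd_$n)) {
    cols <- which(sd_$idx == i)
    Y <- sim[, cols, drop = FALSE]
    yobs <- sd_$y[cols]
    E <- colMeans(Y)
    V <- stats::cov(Y) + diag(1e-8, length(cols))
    L <- chol(V)
    dec_obs <- backsolve(L, yobs - E, transpose = TRUE)
    dec_sim <- backsolve(L, t(Y) - E, transpose = TRUE)  # T x n_sim
    rank_frac <- (rowSums(dec_sim < dec_obs) + 0.5) / (n_sim + 1)
    npde_all[cols] <- stats::qnorm(pmin(pmax(rank_frac, 1 / (2 * n_sim)),
                                        1 - 1 / (2 * n_sim)))
  }
  keep <- !sd_$cens
  x <- npde_all[keep]
  nn <- length(x)
  stat_var <- (nn - 1) * stats::var(x) / 1  # chi-square under H0: var = 1
  p_var <- 2 * min(stats::pchisq(stat_var, nn - 1),
                   stats::pchisq(stat_var, nn - 1, lower.tail = FALSE))
  structure(list(npde = x, mean = mean(x), variance = stats::var(x),
                 p_mean = stats::t.test(x)$p.value,
                 p_var = p_var,
                 p_normal = stats::shapiro.test(x)$p.value,
                 p_ks = suppressWarnings(stats::ks.test(x, "pnorm")$p.value),
                 n_sim = n_sim, seed = seed),
            class = "npde_result")
}

#' Goodness-of-fit tables
#'
#' Observed vs population-predicted (typical parameters) and
#' individual-predicted (empirical Bayes parameters) concentrations, with
#' population and individual weighted residuals under the proportional
#' error model, against time and against the predictions.
#'
#' @param fit a [saem_fit()] or [population_fit()] object.
#' @return data.frame with one row per (uncensored) observation: `ID`,
#'   `TIME`, `observed`, `pop_pred`, `ind_pred`, `pwres`, `iwres`.
#' @export
gof_tables <- function(fit) {
  stopifnot(inherits(fit, "saem_fit"))
  sd_ <- fit$saem_data
  structure <- fit$structure
  n <- sd_$n; p <- structure$npar
  theta_pop <- matrix(fit$theta_hat, n, p, byrow = TRUE)
  pop <- structure$predict(theta_pop, sd_$dose, sd_$idx, sd_$times)
  ind <- structure$predict(exp(fit$phi_map), sd_$dose, sd_$idx, sd_$times)
  keep <- !sd_$cens
  data.frame(ID = sd_$ids[sd_$idx[keep]], TIME = sd_$times[keep],
             observed = sd_$y[keep], pop_pred = pop[keep],
             ind_pred = ind[keep],
             pwres = (sd_$y[keep] - pop[keep]) / (fit$b_hat * pop[keep]),
             iwres = (sd_$y[keep] - ind[keep]) / (fit$b_hat * ind[keep]))
}
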
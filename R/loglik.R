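# multivariate normal log-density via Cholesky (y: T-vector, V: T x T)
.ldmvnorm <- function(y, m, V) {
  L <- chol(V)
  z <- backsolve(L, y - m, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# finite-difference sensitivity of the prediction to phi at phi0 (T x p)
.sens_matrix <- function(phi0, dose, times, structure, h = 1e-4) {
  p <- length(phi0)
  G <- matrix(0, length(times), p)
  for (j in seq_len(p)) {
    up <- phi0; up[j] <- up[j] + h
    dn <- phi0; dn[j] <- dn[j] - h
    fu <- structure$predict(matrix(exp(up), 1), dose, rep(1L, length(times)), times)
    fd <- structure$predict(matrix(exp(dn), 1), dose, rep(1L, length(times)), times)
    G[, j] <- (fu - fd) / (2 * h)
  }
  G
}

# linearized population log-likelihood: model linearized in phi about the
# conditional modes, giving an explicit Gaussian marginal per subject
.ll_linearized <- function(psi, fit, cache) {
  p <- fit$structure$npar
  mu <- psi[seq_len(p)]
  omega <- psi[p + seq_len(p)]
  b <- psi[2 * p + 1]
  if (any(omega < 0) || b <= 0) return(-Inf)
  ll <- 0
  for (i in seq_along(cache)) {
    ci <- cache[[i]]
    m <- ci$f + ci$G %*% (mu - ci$phi)
    V <- ci$G %*% (diag(omega^2, p)) %*% t(ci$G) + diag(b^2 * ci$f^2, length(ci$f))
    diag(V) <- diag(V) + 1e-10
    val <- try(.ldmvnorm(ci$y, m, V), silent = TRUE)
    if (inherits(val, "try-error")) return(-Inf)
    ll <- ll + val
  }
  ll
}

# RSE% of (theta, omega, b) from the curvature of the linearized likelihood
.rse_linearized <- function(fit) {
  sd_ <- fit$saem_data
  structure <- fit$structure
  p <- structure$npar
  cache <- lapply(seq_len(sd_$n), function(i) {
    rows <- sd_$idx == i & !sd_$cens
    ti <- sd_$times[rows]
    phi0 <- fit$phi_map[i, ]
    f <- structure$predict(matrix(exp(phi0), 1), sd_$dose[i],
                           rep(1L, sum(rows)), ti)
    list(y = sd_$y[rows], f = f, phi = phi0,
         G = .sens_matrix(phi0, sd_$dose[i], ti, structure))
  })
  psi0 <- c(log(fit$theta_hat), fit$omega_hat, fit$b_hat)
  q <- length(psi0)
  hh <- pmax(1e-3 * abs(psi0), 1e-4)
  # omega and b must stay positive under the finite-difference steps
  pos <- (p + 1L):q
  hh[pos] <- pmin(hh[pos], 0.49 * pmax(psi0[pos], 1e-8))
  fval <- function(psi) .ll_linearized(psi, fit, cache)
  H <- matrix(NA_real_, q, q)
  f0 <- fval(psi0)
  for (j in seq_len(q)) {
    for (l in j:q) {
      ej <- el <- numeric(q); ej[j] <- hh[j]; el[l] <- hh[l]
      if (j == l) {
        H[j, j] <- (fval(psi0 + ej) - 2 * f0 + fval(psi0 - ej)) / hh[j]^2
      } else {
        H[j, l] <- H[l, j] <-
          (fval(psi0 + ej + el) - fval(psi0 + ej - el) -
             fval(psi0 - ej + el) + fval(psi0 - ej - el)) / (4 * hh[j] * hh[l])
      }
    }
  }
  fim <- -H
  se <- rep(NA_real_, q)
  cov <- NULL
  for (ridge in c(0, 1e-8, 1e-5, 1e-2) * max(1, max(abs(diag(fim))))) {
    cc <- try(solve(fim + diag(ridge, q)), silent = TRUE)
    if (!inherits(cc, "try-error") && all(is.finite(diag(cc))) &&
        all(diag(cc) > 0)) { cov <- cc; break }
  }
  if (any(!is.finite(fim))) return(stats::setNames(rep(NA_real_, q),
    c(names(fit$theta_hat), paste0("omega_", names(fit$omega_hat)), "b")))
  if (is.null(cov)) {  # eigenvalue pseudo-inverse for near-singular designs
    eg <- eigen(fim, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    if (any(pos))
      cov <- eg$vectors[, pos, drop = FALSE] %*%
        diag(1 / eg$values[pos], sum(pos)) %*%
        t(eg$vectors[, pos, drop = FALSE])
  }
  if (!is.null(cov)) {
    d <- diag(cov)
    ok <- is.finite(d) & d >= 0
    se[ok] <- sqrt(d[ok])
  }
  # theta is log-parameterized: SE on the log scale is already relative
  rse <- c(100 * se[seq_len(p)],
           100 * se[p + seq_len(p)] / fit$omega_hat,
           100 * se[2 * p + 1] / fit$b_hat)
  stats::setNames(rse, c(names(fit$theta_hat),
                         paste0("omega_", names(fit$omega_hat)), "b"))
}

#' Importance-sampling log-likelihood
#'
#' Estimates the marginal log-likelihood of a fitted model by importance
#' sampling: for each subject, draws are taken from a Gaussian proposal
#' centred at the conditional mode with the (inflated) MCMC posterior
#' covariance, and the marginal density integral over the random effects is
#' averaged. The reported standard error decreases with `n_samples`.
#'
#' @param fit a [saem_fit()] result.
#' @param n_samples importance-sampling draws per subject.
#' @param seed integer seed.
#' @param inflate proposal covariance inflation factor.
#' @return list with `ll` (log-likelihood), `se` (Monte-Carlo standard
#'   error) and `n_samples`.
#' @export
log_likelihood_is <- function(fit, n_samples = 1000, seed = 1, inflate = 2) {
  stopifnot(inherits(fit, "saem_fit"))
  sd_ <- fit$saem_data
  structure <- fit$structure
  p <- structure$npar
  mu <- log(fit$theta_hat)
  omega2 <- pmax(fit$omega_hat^2, 1e-10)
  b <- fit$b_hat
  set.seed(as.integer(seed))
  M <- as.integer(n_samples)
  ll <- 0; var_sum <- 0
  for (i in seq_len(sd_$n)) {
    rows <- sd_$idx == i
    ti <- sd_$times[rows]; yi <- sd_$y[rows]; ci <- sd_$cens[rows]
    Tn <- length(ti)
    C <- fit$post_cov[[i]] * inflate
    diag(C) <- diag(C) * (1 + 1e-6) + 1e-12  # relative ridge: the proposal
    # must stay on the posterior's scale even when the random effects collapse
    L <- chol(C)
    Z <- matrix(stats::rnorm(M * p), M, p)
    phi <- matrix(fit$phi_map[i, ], M, p, byrow = TRUE) + Z %*% L
    logq <- -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(L))) + rowSums(Z^2))
    logprior <- -0.5 * rowSums(sweep(phi, 2, unname(mu))^2 /
                                 rep(omega2, each = M)) -
      0.5 * sum(log(2 * pi * omega2))
    f <- structure$predict(exp(phi), sd_$dose[i],
                           rep(seq_len(M), each = Tn), rep(ti, M))
    fm <- matrix(f, M, Tn, byrow = TRUE)
    bad <- rowSums(!is.finite(fm) | fm <= 0) > 0
    fm[fm <= 0 | !is.finite(fm)] <- 1  # placeholder, masked below
    lmat <- matrix(0, M, Tn)
    if (any(!ci))
      lmat[, !ci] <- stats::dnorm(matrix(yi[!ci], M, sum(!ci), byrow = TRUE),
                                  fm[, !ci, drop = FALSE],
                                  b * fm[, !ci, drop = FALSE], log = TRUE)
    if (any(ci))
      lmat[, ci] <- stats::pnorm(matrix(yi[ci], M, sum(ci), byrow = TRUE),
                                 fm[, ci, drop = FALSE],
                                 b * fm[, ci, drop = FALSE], log.p = TRUE)
    loglik <- rowSums(lmat)
    loglik[bad] <- -Inf
    lw <- loglik + logprior - logq
    mx <- max(lw)
    if (!is.finite(mx)) return(list(ll = -Inf, se = Inf, n_samples = M))
    w <- exp(lw - mx)
    ll <- ll + mx + log(mean(w))
    var_sum <- var_sum + stats::var(w) / (M * mean(w)^2)
  }
  list(ll = ll, se = sqrt(var_sum), n_samples = M)
}

#' Compare fitted models by AIC, BIC and likelihood-ratio tests
#'
#' @param fits named list of [saem_fit()] results fitted to the same data.
#' @param nested optional list of `c(full, reduced)` name pairs; for each,
#'   the LRT statistic `2 (LL_full - LL_reduced)` is referred to a
#'   chi-square with the parameter-count difference as degrees of freedom.
#' @return list with `criteria` (model, n_par, log_lik, aic, bic,
#'   delta_aic, delta_bic) and `lrt` (full, reduced, statistic, df,
#'   p_value; `NULL` when no pairs are declared).
#' @export
compare_models <- function(fits, nested = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1, !is.null(names(fits)))
  crit <- data.frame(
    model = names(fits),
    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
    log_lik = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"))
  crit$delta_aic <- crit$aic - min(crit$aic)
  crit$delta_bic <- crit$bic - min(crit$bic)
  rownames(crit) <- NULL
  lrt <- NULL
  if (!is.null(nested)) {
    lrt <- do.call(rbind, lapply(nested, function(pair) {
      full <- fits[[pair[1]]]; red <- fits[[pair[2]]]
      df <- full$n_par - red$n_par
      if (df <= 0) stop("nested pair must be (full, reduced)", call. = FALSE)
      stat <- max(2 * (full$log_likelihood - red$log_likelihood), 0)
      data.frame(full = pair[1], reduced = pair[2], statistic = stat,
                 df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
    }))
    rownames(lrt) <- NULL
  }
  list(criteria = crit, lrt = lrt)
}
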
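# shared fixtures: reference parameter sets and desk-scale fit settings

iv_params <- function() micro_params_iv(V = 3.60, k10 = 0.17, k12 = 1.20, k21 = 0.26)
oral_params <- function() micro_params_oral(V = 22.20, k10 = 0.43, k12 = 4.09,
                                            k21 = 0.44, ka = 1.88)

iv_typical <- c(V = 3.60, k10 = 0.17, k12 = 1.20, k21 = 0.26)
oral_typical <- c(V = 22.20, k10 = 0.43, k12 = 4.09, k21 = 0.44, ka = 1.88)

# random positive micro-constant sets with well-separated rates
random_iv_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      p <- list(V = stats::runif(1, 0.5, 30), k10 = stats::runif(1, 0.02, 1),
                k12 = stats::runif(1, 0.05, 4), k21 = stats::runif(1, 0.05, 2))
      s <- p$k10 + p$k12 + p$k21
      if (s^2 - 4 * p$k10 * p$k21 > 1e-4 * s^2) break
    }
    do.call(micro_params_iv, p)
  })
}

quick_settings <- function(seed = 1, ...) {
  fit_settings(n_burn = 120, n_smooth = 80, n_ll = 300, seed = seed, ...)
}
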
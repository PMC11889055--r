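# Shared fixtures and independent oracles for the test suite.

# Brute-force GPCM category probabilities: direct exponentials of the
# cumulative eta sums, no log-space tricks. Independent of gpcm_prob().
oracle_gpcm_prob <- function(theta, alpha, betas) {
  eta <- alpha * (theta - betas)
  w <- c(1, exp(cumsum(eta)))
  w / sum(w)
}

oracle_expected_score <- function(theta, alpha, betas) {
  sum(seq(0, length(betas)) * oracle_gpcm_prob(theta, alpha, betas))
}

# small long-format parameter table for two groups sharing `k` items
fixture_params <- function(k = 5, groups = c("F", "R"), shift_r = 0) {
  base <- tibble::tibble(
    item = sprintf("it%d", seq_len(k)),
    alpha = seq(0.8, 1.4, length.out = k),
    beta1 = seq(-1, 0.5, length.out = k),
    beta2 = seq(0, 1.5, length.out = k))
  out <- dplyr::bind_rows(
    dplyr::mutate(base, group = groups[1]),
    dplyr::mutate(base, group = groups[2],
                  beta1 = beta1 + shift_r,
                  beta2 = beta2 + shift_r))
  out[c("group", "item", "alpha", "beta1", "beta2")]
}

# small three-group truth configuration used across sampler tests
fixture_truth <- function(n = 300, k = 16,
                          means = c(0, 0.4, 1.0)) {
  truth_config(
    groups = tibble::tibble(group = c("G1", "G2", "G3"), n = rep(n, 3),
                            mean = means, var = c(1, 1, 1)),
    items = tibble::tibble(item = sprintf("it%02d", seq_len(k)),
                           alpha = rep(c(0.8, 1.1, 1.4, 1.0),
                                       length.out = k),
                           beta1 = rep(c(-0.5, 0, 0.5, 1.0),
                                       each = 4, length.out = k),
                           beta2 = rep(c(0.5, 1.0, 1.5, 2.0),
                                       each = 4, length.out = k)))
}

fast_mcmc <- function(n_burn = 100, n_keep = 300, seed = 1, ...) {
  mcmc_config(n_burn = n_burn, n_keep = n_keep, seed = seed, ...)
}

# one moderately sized fit, computed once per test run and reused
shared_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cohorts(fixture_truth(n = 300, k = 16), seed = 2025)
      fit <- fit_mggpcm(sim$data,
                        mcmc = mcmc_config(n_burn = 200, n_keep = 800,
                                           seed = 11))
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})
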
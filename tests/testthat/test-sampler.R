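test_that("identification rescaling enforces constraints, preserves likelihood", {
  sim <- simulate_cohorts(fixture_truth(n = 40, k = 6), seed = 14)
  ds <- sim$data
  params <- sim$truth$params  # already identified
  theta <- sim$truth$theta$theta
  state <- list(params = params, theta = theta,
                group_of = ds$persons$group,
                mu_theta = sim$truth$mu, tau = 1 / sim$truth$sigma)

  # already-identified state is a fixed point
  out <- apply_identification(state)
  expect_equal(out$params$alpha, params$alpha, tolerance = 1e-12)
  expect_equal(out$theta, theta, tolerance = 1e-12)

  # shift all of one group's thresholds by +0.3: recentered, traits follow
  shifted <- state
  sel <- shifted$params$group == "G2"
  shifted$params$beta1[sel] <- shifted$params$beta1[sel] + 0.3
  shifted$params$beta2[sel] <- shifted$params$beta2[sel] + 0.3
  ll_before <- loglik_gpcm(ds, shifted$params, shifted$theta)
  out <- apply_identification(shifted)
  ll_after <- loglik_gpcm(ds, out$params, out$theta)
  expect_equal(ll_after, ll_before, tolerance = 1e-10)
  for (g in c("G1", "G2", "G3")) {
    pg <- out$params[out$params$group == g, ]
    expect_lt(abs(mean(c(pg$beta1, pg$beta2))), 1e-8)
    expect_lt(abs(prod(pg$alpha) - 1), 1e-8)
  }
  g2 <- out$params$group == "G2"
  expect_equal(out$theta[ds$persons$group == "G2"],
               theta[ds$persons$group == "G2"] - 0.3, tolerance = 1e-10)
  expect_equal(out$mu_theta[["G2"]], state$mu_theta[["G2"]] - 0.3,
               tolerance = 1e-10)

  # double all of one group's discriminations: product back to 1, tau / 4
  scaled <- state
  scaled$params$alpha[sel] <- scaled$params$alpha[sel] * 2
  ll_before <- loglik_gpcm(ds, scaled$params, scaled$theta)
  out2 <- apply_identification(scaled)
  expect_equal(prod(out2$params$alpha[g2]), 1, tolerance = 1e-8)
  expect_equal(out2$tau[["G2"]], state$tau[["G2"]] / 4, tolerance = 1e-10)
  expect_equal(loglik_gpcm(ds, out2$params, out2$theta), ll_before,
               tolerance = 1e-10)
})

test_that("fits are reproducible given the seed", {
  sim <- simulate_cohorts(fixture_truth(n = 40, k = 4), seed = 5)
  f1 <- fit_mggpcm(sim$data, mcmc = fast_mcmc(n_burn = 50, n_keep = 60,
                                              seed = 3))
  f2 <- fit_mggpcm(sim$data, mcmc = fast_mcmc(n_burn = 50, n_keep = 60,
                                              seed = 3))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$theta_mean, f2$theta_mean)
})

test_that("a short-form group yields draws only for administered pairs", {
  cfg <- fixture_truth(n = 60, k = 8)
  cfg$admin["G3", 1:5] <- FALSE  # G3 sees only 3 of 8 items
  sim <- simulate_cohorts(cfg, seed = 6)
  fit <- fit_mggpcm(sim$data, mcmc = fast_mcmc(n_burn = 60, n_keep = 80,
                                               seed = 2))
  nms <- colnames(fit$draws[[1]])
  expect_false(any(grepl("alpha\\[G3,it01\\]", nms)))
  expect_true(any(grepl("alpha\\[G3,it08\\]", nms)))
  expect_equal(sum(grepl("^alpha\\[", nms)), 8 + 8 + 3)
  # every retained draw satisfies both identification constraints
  d <- fit$draws[[1]]
  for (g in c("G1", "G3")) {
    adm <- fit$items[fit$admin[g, ]]
    a_cols <- paste0("alpha[", g, ",", adm, "]")
    b_cols <- c(paste0("beta1[", g, ",", adm, "]"),
                paste0("beta2[", g, ",", adm, "]"))
    expect_lt(max(abs(apply(d[, a_cols, drop = FALSE], 1, prod) - 1)), 1e-8)
    expect_lt(max(abs(rowMeans(d[, b_cols, drop = FALSE]))), 1e-8)
  }
})

test_that("group-mean contrasts and traits are recovered on synthetic data", {
  sh <- shared_fit()
  fit <- sh$fit; truth <- sh$sim$truth
  s <- tidy(fit)
  mu <- s[s$parameter == "mu", ]
  est <- stats::setNames(mu$mean, mu$group)
  sd_ <- stats::setNames(mu$sd, mu$group)
  for (pair in list(c("G2", "G1"), c("G3", "G1"), c("G3", "G2"))) {
    contrast <- est[pair[1]] - est[pair[2]]
    truth_c <- truth$mu[pair[1]] - truth$mu[pair[2]]
    expect_lt(abs(contrast - truth_c),
              3 * sqrt(sd_[pair[1]]^2 + sd_[pair[2]]^2))
  }
  sc <- score_persons(fit)
  expect_gt(stats::cor(sc$theta_mean, truth$theta$theta), 0.8)
})

test_that("harmonized scores order and summarize persons sensibly", {
  sh <- shared_fit()
  fit <- sh$fit
  sc <- score_persons(fit)
  ds <- sh$sim$data
  # an all-zero responder sits below their group's mean trait
  sums <- rowSums(ds$responses)
  zero <- which(sums == 0)[1]
  skip_if(is.na(zero), "fixture produced no all-zero responder")
  g <- as.character(ds$persons$group[zero])
  s <- tidy(fit)
  mu_g <- s$mean[s$parameter == "mu" & s$group == g]
  expect_lt(sc$theta_mean[zero], mu_g)
  # identical response patterns in the same group get matching estimates
  # (up to Monte-Carlo error of the posterior means)
  pats <- apply(ds$responses, 1, paste, collapse = ",")
  key <- paste(ds$persons$group, pats)
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  twin_groups <- split(dup, key[dup])
  twin_groups <- Filter(function(x) length(x) >= 2, twin_groups)
  skip_if(length(twin_groups) == 0, "fixture produced no duplicate patterns")
  pair <- twin_groups[[1]][1:2]
  expect_lt(abs(sc$theta_mean[pair[1]] - sc$theta_mean[pair[2]]),
            4 * mean(sc$theta_sd[pair]) / sqrt(50))
})

test_that("a data-free fit reproduces the group-mean prior", {
  df <- tibble::tibble(group = character(), i1 = integer(), i2 = integer())
  mask <- matrix(TRUE, 2, 2, dimnames = list(c("A", "B"), c("i1", "i2")))
  ds <- response_dataset(df, items = c("i1", "i2"), groups = c("A", "B"),
                         admin_mask = mask)
  fit <- fit_mggpcm(ds, mcmc = mcmc_config(n_burn = 100, n_keep = 3000,
                                           seed = 31),
                    identify = FALSE)
  d <- do.call(rbind, fit$draws)
  for (g in c("A", "B")) {
    mu_d <- d[, paste0("mu[", g, "]")]
    expect_lt(abs(mean(mu_d)), 0.25)       # prior mean 0, MC error
    expect_lt(abs(stats::var(mu_d) - 10), 1.2)  # prior variance 10
  }
})

test_that("convergence diagnostics flag stuck chains and discount autocorrelation", {
  set.seed(77)
  # i.i.d. draws: R-hat near 1, healthy ESS
  iid <- matrix(stats::rnorm(4000), 2000, 2,
                dimnames = list(NULL, c("a", "b")))
  diag <- convergence_diagnostics(iid)
  expect_true(all(diag$rhat < 1.02))
  expect_false(any(diag$flagged))

  # two chains stuck at different constants: flagged
  const <- list(matrix(1, 100, 1, dimnames = list(NULL, "p")),
                matrix(2, 100, 1, dimnames = list(NULL, "p")))
  expect_true(convergence_diagnostics(const)$flagged)

  # AR(1) with rho = 0.9: ESS near n (1 - rho) / (1 + rho)
  n <- 20000; rho <- 0.9
  x <- stats::filter(stats::rnorm(n), rho, method = "recursive")
  ar <- matrix(as.numeric(x), n, 1, dimnames = list(NULL, "p"))
  ess <- convergence_diagnostics(ar)$ess
  expect_lt(abs(ess - n * (1 - rho) / (1 + rho)) / (n * (1 - rho) / (1 + rho)),
            0.25)
  expect_error(convergence_diagnostics(matrix(rnorm(40), 40, 1)),
               "at least 50")
})

test_that("tidy and glance summarize the fit for downstream use", {
  sh <- shared_fit()
  s <- tidy(sh$fit)
  expect_true(all(c("term", "parameter", "group", "item", "mean", "sd",
                    "conf.low", "conf.high", "rhat", "ess") %in% names(s)))
  expect_true(all(s$conf.low <= s$conf.high))
  expect_equal(sum(s$parameter == "mu"), 3)
  g <- glance(sh$fit)
  expect_equal(g$n_persons, 900)
  expect_equal(g$n_draws, 800)
  expect_gt(g$accept_theta, 0.15)
  expect_lt(g$accept_theta, 0.6)
})
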
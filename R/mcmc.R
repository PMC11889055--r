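#' MCMC settings for the multi-group GPCM sampler
#'
#' @param n_burn Burn-in iterations (discarded; proposal scales adapt here).
#' @param n_keep Post-burn-in iterations characterizing the posterior.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param n_chains Number of independent chains, run sequentially.
#' @param adapt_every Burn-in interval (iterations) between proposal-scale
#'   updates.
#' @param target_accept Acceptance rate the adaptation aims for.
#' @param keep_person_draws Store all person-trait draws (memory-heavy for
#'   large samples); running mean/SD are always kept.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 1000, n_keep = 10000, thin = 1, seed = 1,
                        n_chains = 1, adapt_every = 25, target_accept = 0.3,
                        keep_person_draws = FALSE) {
  stopifnot(n_burn >= 0, n_keep >= 1, thin >= 1, n_chains >= 1)
  structure(list(n_burn = n_burn, n_keep = n_keep, thin = thin, seed = seed,
                 n_chains = n_chains, adapt_every = adapt_every,
                 target_accept = target_accept,
                 keep_person_draws = keep_person_draws),
            class = "mcmc_config")
}

#' Prior settings for the hierarchical multi-group GPCM
#'
#' Defaults encode the quasi-fixed-effects specification: diffuse normal
#' priors (precision 0.1, variance 10) on group trait means and on
#' group-specific item-parameter deviations around the general item
#' parameters, a Gamma prior on group precisions, and an inverse-Wishart
#' hyperprior on the item-parameter covariance.
#'
#' @param mu_prec Prior precision of group trait means (mean 0).
#' @param tau_shape,tau_scale Gamma prior on group precisions
#'   \eqn{\tau_j}. `tau_gamma` selects whether `tau_scale` is read as a
#'   rate (default; prior mean `tau_shape / tau_scale` = 10) or as a scale
#'   (prior mean `tau_shape * tau_scale`).
#' @param tau_gamma `"rate"` or `"scale"` interpretation of `tau_scale`.
#' @param q_prec Precision of group-specific item-parameter deviations
#'   around the general item parameters (`Q = q_prec * I`); the small
#'   default makes them quasi-fixed effects.
#' @param R 3x3 precision matrix of the grand-mean prior, also the
#'   inverse-Wishart scale matrix.
#' @param d Inverse-Wishart degrees of freedom; must exceed the number of
#'   item parameters minus one (here 3 - 1 = 2).
#' @param mu_alpha,mu_beta Grand prior means for discriminations (1) and
#'   thresholds (0).
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(mu_prec = 0.1, tau_shape = 1, tau_scale = 0.1,
                         tau_gamma = c("rate", "scale"), q_prec = 0.1,
                         R = diag(3), d = 3, mu_alpha = 1, mu_beta = 0) {
  tau_gamma <- match.arg(tau_gamma)
  tau_rate <- if (tau_gamma == "rate") tau_scale else 1 / tau_scale
  stopifnot(mu_prec > 0, tau_shape > 0, tau_rate > 0, q_prec > 0,
            nrow(R) == 3, d > 2)
  structure(list(mu_prec = mu_prec, tau_shape = tau_shape,
                 tau_rate = tau_rate, q_prec = q_prec, R = R, d = d,
                 mu_k = c(mu_alpha, mu_beta, mu_beta)),
            class = "prior_config")
}

#' Fit the Bayesian multi-group GPCM
#'
#' Metropolis-within-Gibbs sampler for a GPCM with group-specific item
#' parameters: random-walk Metropolis for person traits and item parameters
#' (discriminations proposed on the log scale, keeping them positive),
#' conjugate Gibbs updates for group trait means/precisions and for the
#' item-parameter hierarchy (general item parameters, grand mean,
#' inverse-Wishart covariance). After every full scan the per-group
#' identification restrictions — mean threshold 0 and product of
#' discriminations 1 over administered items — are imposed by the
#' likelihood-preserving rescaling, so every stored draw is identified.
#'
#' @param ds A [response_dataset()] (complete cases recommended).
#' @param items Items to analyze; default all.
#' @param mcmc An [mcmc_config()].
#' @param priors A [prior_config()].
#' @param identify Impose the identification restrictions each scan
#'   (default `TRUE`; disable only to inspect the unconstrained prior).
#' @param verbose Print progress to stderr.
#' @return An object of class `mggpcm_fit` with per-chain draw matrices,
#'   person-trait posterior means/SDs, acceptance rates, and the data/config
#'   used. See [tidy.mggpcm_fit()], [score_persons()], [item_parameters()],
#'   [dtf_table()].
#' @export
fit_mggpcm <- function(ds, items = NULL, mcmc = mcmc_config(),
                       priors = prior_config(), identify = TRUE,
                       verbose = FALSE) {
  stopifnot(inherits(ds, "response_dataset"), ds$C == 2)
  items <- items %||% item_names(ds)
  admin <- ds$admin[, items, drop = FALSE]
  if (nrow(admin) < 2) stop("invariance analysis needs at least 2 groups")
  if (any(rowSums(admin) < 2)) {
    stop("every group needs at least 2 administered items for identification")
  }
  Y <- ds$responses[, items, drop = FALSE]
  grp <- as.integer(ds$persons$group)

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    chains[[ch]] <- run_chain(Y, grp, admin, priors, mcmc,
                              seed = mcmc$seed + ch - 1,
                              identify = identify, verbose = verbose)
  }

  # pool person-trait moments across chains
  n_d <- chains[[1]]$n_draws
  if (length(chains[[1]]$theta_mean) == 0) {
    tm <- tsd <- numeric(0)
  } else {
  tm <- rowMeans(sapply(chains, `[[`, "theta_mean"))
  if (mcmc$n_chains > 1) {
    within <- rowMeans(sapply(chains, function(c) c$theta_sd^2))
    between <- rowMeans(sapply(chains, function(c) (c$theta_mean - tm)^2))
    tsd <- sqrt(within + between)
  } else {
    tsd <- chains[[1]]$theta_sd
  }
  }

  structure(list(
    draws = lapply(chains, `[[`, "draws"),
    theta_mean = tm, theta_sd = tsd,
    theta_draws = if (mcmc$keep_person_draws)
      lapply(chains, `[[`, "theta_draws"),
    accept = list(theta = mean(sapply(chains, function(c) c$acc_theta)),
                  item = mean(sapply(chains, function(c) c$acc_item))),
    items = items, groups = rownames(admin), admin = admin, C = ds$C,
    persons = ds$persons, data = ds,
    n_draws = n_d, mcmc = mcmc, priors = priors, identify = identify
  ), class = "mggpcm_fit")
}

#' @export
print.mggpcm_fit <- function(x, ...) {
  cat("<mggpcm_fit> multi-group GPCM\n")
  cat("  persons:", length(x$theta_mean), " items:", length(x$items),
      " groups:", length(x$groups), "\n")
  cat("  chains:", length(x$draws), "x", x$n_draws, "draws",
      sprintf("(burn %d, thin %d)\n", x$mcmc$n_burn, x$mcmc$thin))
  cat(sprintf("  acceptance: theta %.2f, item %.2f\n",
              x$accept$theta, x$accept$item))
  invisible(x)
}

# ---- chain runner ----------------------------------------------------------

run_chain <- function(Y, grp, admin, prior, cfg, seed, identify, verbose) {
  set.seed(seed)
  J <- nrow(admin); K <- ncol(admin); N <- nrow(Y)
  groups <- rownames(admin); items <- colnames(admin)
  q <- prior$q_prec; sd_q <- sqrt(1 / q)

  # --- initialization: data-driven and deterministic
  admN <- admin[grp, , drop = FALSE]
  obs <- !is.na(Y) & admN
  if (N > 0) {
    prop_score <- rowSums(Y * obs, na.rm = TRUE) / pmax(rowSums(obs), 1)
    theta <- as.numeric(scale(prop_score))
    theta[!is.finite(theta)] <- 0
  } else theta <- numeric(0)

  alpha <- ifelse(admin, 1, NA_real_)
  b1 <- b2 <- matrix(NA_real_, J, K, dimnames = dimnames(admin))
  for (j in seq_len(J)) for (k in seq_len(K)) {
    if (!admin[j, k]) next
    y <- Y[grp == j, k]
    cnt <- tabulate(y + 1L, 3L) + 0.5
    b1[j, k] <- clamp(log(cnt[1] / cnt[2]), -2, 2)
    b2[j, k] <- clamp(log(cnt[2] / cnt[3]), -2, 2)
  }
  n_j <- tabulate(grp, J)
  mu <- vapply(seq_len(J), function(j)
    if (n_j[j] > 0) mean(theta[grp == j]) else 0, 0)
  tau <- rep(1, J)
  xi <- rbind(alpha = rep(1, K),
              beta1 = ifelse(colSums(admin) > 0, colMeans(b1, na.rm = TRUE), 0),
              beta2 = ifelse(colSums(admin) > 0, colMeans(b2, na.rm = TRUE), 0))
  xi[!is.finite(xi)] <- 0
  xi0 <- prior$mu_k
  Sigma <- diag(3)

  # --- proposal scales
  st <- rep(0.6, N)
  sit <- ifelse(admin, 0.15, NA_real_)
  acc_t_win <- rep(0, N); acc_i_win <- matrix(0, J, K); n_win <- 0
  acc_t_tot <- 0; acc_i_tot <- 0; n_tot <- 0

  pairs <- which(admin, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  par_names <- c(paste0("mu[", groups, "]"), paste0("tau[", groups, "]"),
                 as.vector(t(outer(seq_len(nrow(pairs)), c("alpha", "beta1", "beta2"),
                   function(i, p) paste0(p, "[", groups[pairs[i, 1]], ",",
                                         items[pairs[i, 2]], "]")))))
  n_draws <- floor(cfg$n_keep / cfg$thin)
  draws <- matrix(NA_real_, n_draws, length(par_names),
                  dimnames = list(NULL, par_names))
  theta_draws <- if (cfg$keep_person_draws)
    matrix(NA_real_, n_draws, N) else NULL
  w_n <- 0; w_mean <- rep(0, N); w_m2 <- rep(0, N)
  d_i <- 0

  total <- cfg$n_burn + cfg$n_keep
  for (it in seq_len(total)) {
    beta <- list(b1, b2)
    lp_cells <- cell_logprob(theta, grp, alpha, beta, Y)

    # --- person traits: elementwise random-walk Metropolis
    if (N > 0) {
      ll_cur <- rowSums(lp_cells, na.rm = TRUE)
      thp <- theta + st * stats::rnorm(N)
      lp_prop <- cell_logprob(thp, grp, alpha, beta, Y)
      ll_prop <- rowSums(lp_prop, na.rm = TRUE)
      sd_g <- 1 / sqrt(tau[grp])
      logr <- ll_prop + stats::dnorm(thp, mu[grp], sd_g, log = TRUE) -
        ll_cur - stats::dnorm(theta, mu[grp], sd_g, log = TRUE)
      acc <- log(stats::runif(N)) < logr
      theta[acc] <- thp[acc]
      lp_cells[acc, ] <- lp_prop[acc, ]
      acc_t_win <- acc_t_win + acc
      if (it > cfg$n_burn) acc_t_tot <- acc_t_tot + mean(acc)
    }

    # --- item parameters: joint (log alpha, beta1, beta2) proposal per
    #     administered group-item cell; independence across cells given theta
    la_p <- log(alpha) + sit * matrix(stats::rnorm(J * K), J, K)
    alpha_p <- exp(la_p)
    b1_p <- b1 + sit * matrix(stats::rnorm(J * K), J, K)
    b2_p <- b2 + sit * matrix(stats::rnorm(J * K), J, K)
    lp_prop <- cell_logprob(theta, grp, alpha_p, list(b1_p, b2_p), Y)
    gll_cur <- group_item_sum(lp_cells, grp, J, K)
    gll_prop <- group_item_sum(lp_prop, grp, J, K)
    xiA <- matrix(xi[1, ], J, K, byrow = TRUE)
    xiB1 <- matrix(xi[2, ], J, K, byrow = TRUE)
    xiB2 <- matrix(xi[3, ], J, K, byrow = TRUE)
    pr_cur <- stats::dnorm(alpha, xiA, sd_q, log = TRUE) +
      stats::dnorm(b1, xiB1, sd_q, log = TRUE) +
      stats::dnorm(b2, xiB2, sd_q, log = TRUE)
    pr_prop <- stats::dnorm(alpha_p, xiA, sd_q, log = TRUE) +
      stats::dnorm(b1_p, xiB1, sd_q, log = TRUE) +
      stats::dnorm(b2_p, xiB2, sd_q, log = TRUE)
    logr <- gll_prop + pr_prop + la_p - (gll_cur + pr_cur + log(alpha))
    accm <- matrix(log(stats::runif(J * K)), J, K) < logr & admin
    accm[is.na(accm)] <- FALSE
    alpha[accm] <- alpha_p[accm]
    b1[accm] <- b1_p[accm]
    b2[accm] <- b2_p[accm]
    acc_i_win <- acc_i_win + accm
    if (it > cfg$n_burn) {
      acc_i_tot <- acc_i_tot + mean(accm[admin])
      n_tot <- n_tot + 1
    }

    # --- group means and precisions: conjugate Gibbs
    for (j in seq_len(J)) {
      tj <- theta[grp == j]
      pp <- prior$mu_prec + n_j[j] * tau[j]
      pm <- tau[j] * sum(tj) / pp
      mu[j] <- stats::rnorm(1, pm, 1 / sqrt(pp))
      tau[j] <- stats::rgamma(1, prior$tau_shape + n_j[j] / 2,
                              prior$tau_rate + 0.5 * sum((tj - mu[j])^2))
    }

    # --- hierarchy: xi_k, xi_0, Sigma
    Sinv <- chol2inv(chol(Sigma))
    for (k in seq_len(K)) {
      adm_j <- which(admin[, k])
      nk <- length(adm_j)
      P <- Sinv + nk * q * diag(3)
      b <- Sinv %*% xi0 +
        q * c(sum(alpha[adm_j, k]), sum(b1[adm_j, k]), sum(b2[adm_j, k]))
      xi[, k] <- rmvn_prec(P, b)
    }
    P0 <- prior$R + K * Sinv
    b0 <- prior$R %*% prior$mu_k + Sinv %*% rowSums(xi)
    xi0 <- rmvn_prec(P0, b0)
    D <- xi - xi0
    Sc <- prior$R + D %*% t(D)
    W <- stats::rWishart(1, prior$d + K, chol2inv(chol(Sc)))[, , 1]
    Sigma <- chol2inv(chol(W))
    Sigma <- (Sigma + t(Sigma)) / 2

    # --- identification rescaling (likelihood-preserving)
    if (identify) {
      id <- identify_arrays(alpha, list(b1, b2), admin, theta, grp, mu, tau)
      alpha <- id$alpha; b1 <- id$beta[[1]]; b2 <- id$beta[[2]]
      theta <- id$theta; mu <- id$mu; tau <- id$tau
    }

    # --- adaptation during burn-in
    n_win <- n_win + 1
    if (it <= cfg$n_burn && n_win == cfg$adapt_every) {
      if (N > 0) {
        st <- clamp(st * exp(acc_t_win / n_win - cfg$target_accept), 0.02, 5)
      }
      sit <- clamp(sit * exp(acc_i_win / n_win - cfg$target_accept), 0.01, 2)
      acc_t_win[] <- 0; acc_i_win[] <- 0; n_win <- 0
    }
    if (it == cfg$n_burn) { acc_t_win[] <- 0; acc_i_win[] <- 0; n_win <- 0 }

    # --- storage
    if (it > cfg$n_burn && (it - cfg$n_burn) %% cfg$thin == 0 &&
        d_i < n_draws) {
      d_i <- d_i + 1
      draws[d_i, ] <- c(mu, tau,
                        as.vector(t(cbind(alpha[pairs], b1[pairs], b2[pairs]))))
      if (!is.null(theta_draws)) theta_draws[d_i, ] <- theta
      w_n <- w_n + 1
      dlt <- theta - w_mean
      w_mean <- w_mean + dlt / w_n
      w_m2 <- w_m2 + dlt * (theta - w_mean)
    }
    if (verbose && it %% 500 == 0) {
      message(sprintf("iter %d/%d  acc(theta)=%.2f acc(item)=%.2f",
                      it, total, mean(acc_t_win) / max(n_win, 1),
                      mean(acc_i_win[admin]) / max(n_win, 1)))
    }
  }

  list(draws = draws, theta_draws = theta_draws,
       theta_mean = w_mean,
       theta_sd = if (w_n > 1) sqrt(w_m2 / (w_n - 1)) else rep(NA_real_, N),
       acc_theta = if (n_tot > 0 && N > 0) acc_t_tot / n_tot else NA_real_,
       acc_item = if (n_tot > 0) acc_i_tot / n_tot else NA_real_,
       n_draws = d_i, pairs = pairs)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sum an N x K cell matrix into J x K group totals, tolerating empty groups
group_item_sum <- function(lp, grp, J, K) {
  out <- matrix(0, J, K)
  if (nrow(lp) == 0) return(out)
  lp0 <- lp
  lp0[is.na(lp0)] <- 0
  rs <- rowsum(lp0, grp)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# draw from N(P^{-1} b, P^{-1}) given precision P
rmvn_prec <- function(P, b) {
  U <- chol(P)
  mean <- backsolve(U, backsolve(U, b, transpose = TRUE))
  drop(mean + backsolve(U, stats::rnorm(nrow(P))))
}

# ---- identification --------------------------------------------------------

identify_arrays <- function(alpha, beta, admin, theta, grp, mu, tau) {
  J <- nrow(admin)
  for (j in seq_len(J)) {
    adm <- admin[j, ]
    a <- alpha[j, adm]
    if (any(a <= 0, na.rm = TRUE)) stop("non-positive discrimination")
    g <- exp(mean(log(a)))
    bs <- unlist(lapply(beta, function(b) b[j, adm]))
    m <- mean(g * bs)
    alpha[j, adm] <- a / g
    for (c in seq_along(beta)) beta[[c]][j, adm] <- g * beta[[c]][j, adm] - m
    sel <- grp == j
    theta[sel] <- g * theta[sel] - m
    mu[j] <- g * mu[j] - m
    tau[j] <- tau[j] / g^2
  }
  list(alpha = alpha, beta = beta, theta = theta, mu = mu, tau = tau)
}

#' Impose the identification restrictions on a model state
#'
#' Rescales each group's parameters so that, over that group's administered
#' items, the mean threshold is 0 and the product (geometric mean) of
#' discriminations is 1. The transformation — `alpha' = alpha / g`,
#' `beta' = g * beta - m`, `theta' = g * theta - m`, `mu' = g * mu - m`,
#' `tau' = tau / g^2`, with `g` the geometric mean of the group's
#' discriminations and `m` the post-scaling mean threshold — leaves every
#' GPCM category probability, and hence the likelihood, unchanged.
#'
#' @param state A list with elements `params` (long parameter table as in
#'   [tcc()]), and optionally `theta` (person traits), `group_of` (group
#'   label per person), `mu_theta` and `tau` (named per-group vectors).
#' @return The state, transformed; same shape as the input.
#' @export
apply_identification <- function(state) {
  params <- state$params
  groups <- unique(as.character(params$group))
  items <- unique(as.character(params$item))
  bc <- beta_cols(params)
  arr <- params_to_arrays(params, groups, items, length(bc))
  admin <- !is.na(arr$alpha)
  theta <- state$theta %||% numeric(0)
  grp <- match(as.character(state$group_of %||% character(0)), groups)
  mu <- (state$mu_theta %||% stats::setNames(rep(0, length(groups)), groups))[groups]
  tau <- (state$tau %||% stats::setNames(rep(1, length(groups)), groups))[groups]
  id <- identify_arrays(arr$alpha, arr$beta, admin, theta, grp, mu, tau)
  out <- state
  out$params <- arrays_to_params(id$alpha, id$beta, admin)
  if (!is.null(state$theta)) out$theta <- id$theta
  if (!is.null(state$mu_theta)) out$mu_theta <- stats::setNames(id$mu, groups)
  if (!is.null(state$tau)) out$tau <- stats::setNames(id$tau, groups)
  out
}

# ---- posterior summaries ---------------------------------------------------

#' Harmonized person scores
#'
#' Posterior mean and SD of each person's latent trait — the harmonized
#' scores that place respondents from different cohorts and instrument
#' subsets on one common scale.
#'
#' @param fit An [fit_mggpcm()] result.
#' @return A tibble: `person`, `group`, `theta_mean`, `theta_sd`.
#' @export
score_persons <- function(fit) {
  stopifnot(inherits(fit, "mggpcm_fit"))
  tibble::tibble(person = fit$persons$person, group = fit$persons$group,
                 theta_mean = fit$theta_mean, theta_sd = fit$theta_sd)
}

#' Posterior-mean item parameters
#'
#' @param fit An [fit_mggpcm()] result.
#' @return Long tibble `group`, `item`, `alpha`, `beta1`, `beta2` of
#'   posterior means for every administered group-item pair.
#' @export
item_parameters <- function(fit) {
  s <- tidy(fit)
  ip <- s[s$parameter %in% c("alpha", "beta1", "beta2"), ]
  out <- tidyr::pivot_wider(ip[c("group", "item", "parameter", "mean")],
                            names_from = "parameter", values_from = "mean")
  out$group <- factor(out$group, levels = fit$groups)
  dplyr::arrange(out, .data$group, match(.data$item, fit$items))
}

parse_par_names <- function(nms) {
  parameter <- sub("\\[.*", "", nms)
  inside <- sub("^[^\\[]*\\[(.*)\\]$", "\\1", nms)
  group <- sub(",.*", "", inside)
  item <- ifelse(grepl(",", inside), sub("^[^,]*,", "", inside), NA_character_)
  tibble::tibble(term = nms, parameter = parameter, group = group, item = item)
}

#' Tidy posterior summary of a multi-group GPCM fit
#'
#' One row per model parameter (group trait means and precisions, and each
#' administered group-item discrimination/threshold) with posterior mean,
#' SD, central 95% interval, and split-R-hat / effective sample size.
#'
#' @param x An [fit_mggpcm()] result.
#' @param conf_level Central interval coverage (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `parameter`, `group`, `item`,
#'   `mean`, `sd`, `conf.low`, `conf.high`, `rhat`, `ess`.
#' @exportS3Method generics::tidy
tidy.mggpcm_fit <- function(x, conf_level = 0.95, ...) {
  all_draws <- do.call(rbind, x$draws)
  a <- (1 - conf_level) / 2
  qs <- apply(all_draws, 2, stats::quantile, probs = c(a, 1 - a))
  diag <- convergence_diagnostics(x$draws)
  out <- parse_par_names(colnames(all_draws))
  out$mean <- colMeans(all_draws)
  out$sd <- apply(all_draws, 2, stats::sd)
  out$conf.low <- qs[1, ]
  out$conf.high <- qs[2, ]
  out$rhat <- diag$rhat[match(out$term, diag$parameter)]
  out$ess <- diag$ess[match(out$term, diag$parameter)]
  out
}

#' One-line fit summary
#'
#' @param x An [fit_mggpcm()] result.
#' @param ... Unused.
#' @return A one-row tibble: sizes, draw counts, acceptance rates, worst
#'   R-hat and smallest ESS.
#' @exportS3Method generics::glance
glance.mggpcm_fit <- function(x, ...) {
  s <- tidy(x)
  tibble::tibble(n_persons = length(x$theta_mean), n_items = length(x$items),
                 n_groups = length(x$groups), n_chains = length(x$draws),
                 n_draws = x$n_draws * length(x$draws),
                 accept_theta = x$accept$theta, accept_item = x$accept$item,
                 max_rhat = max(s$rhat, na.rm = TRUE),
                 min_ess = min(s$ess, na.rm = TRUE))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---- convergence diagnostics ----------------------------------------------

split_chains <- function(draws) {
  if (is.matrix(draws)) draws <- list(draws)
  out <- list()
  for (m in draws) {
    h <- floor(nrow(m) / 2)
    out <- c(out, list(m[seq_len(h), , drop = FALSE],
                       m[h + seq_len(h), , drop = FALSE]))
  }
  out
}

rhat_one <- function(x) {
  # x: iterations x chains
  n <- nrow(x); m <- ncol(x)
  cm <- colMeans(x)
  if (stats::sd(cm) == 0 && all(apply(x, 2, stats::sd) == 0)) return(NA_real_)
  B <- n * stats::var(cm)
  W <- mean(apply(x, 2, stats::var))
  if (W == 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_one <- function(x) {
  # Geyer initial-monotone-sequence estimator, averaged over chains
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2, stats::var))
  if (W == 0) return(NA_real_)
  max_lag <- min(n - 1, 200)
  rho <- sapply(seq_len(m), function(ch) {
    v <- x[, ch] - mean(x[, ch])
    ac <- stats::acf(v, lag.max = max_lag, plot = FALSE,
                     demean = FALSE)$acf[-1]
    ac
  })
  rho <- c(1, rowMeans(matrix(rho, ncol = m)))
  # Geyer pair sums: truncate at first negative pair, enforce monotone decay
  np <- floor(length(rho) / 2)
  ps <- rho[2 * seq_len(np) - 1] + rho[2 * seq_len(np)]
  neg <- which(ps < 0)
  if (length(neg) > 0) ps <- ps[seq_len(neg[1] - 1)]
  if (length(ps) > 1) ps <- cummin(ps)
  tau_int <- max(2 * sum(ps) - 1, 1e-8)
  min(n * m / tau_int, n * m)
}

#' Split-R-hat and effective sample size per parameter
#'
#' Potential-scale-reduction (split-half, rank-free) and a Geyer
#' initial-monotone-sequence effective sample size for each column of the
#' draw matrices. Parameters with `rhat > 1.05` are flagged.
#'
#' @param draws A draw matrix (iterations x parameters), a list of such
#'   matrices (one per chain), or an [fit_mggpcm()] object.
#' @return A tibble: `parameter`, `rhat`, `ess`, `flagged`.
#' @export
convergence_diagnostics <- function(draws) {
  if (inherits(draws, "mggpcm_fit")) draws <- draws$draws
  if (is.matrix(draws)) draws <- list(draws)
  stopifnot(all(vapply(draws, is.matrix, TRUE)))
  if (nrow(draws[[1]]) < 50) stop("need at least 50 draws per chain")
  halves <- split_chains(draws)
  P <- ncol(draws[[1]])
  rhat <- ess <- numeric(P)
  for (p in seq_len(P)) {
    xs <- sapply(halves, function(m) m[, p])
    rhat[p] <- rhat_one(xs)
    full <- sapply(draws, function(m) m[, p])
    ess[p] <- ess_one(matrix(full, ncol = length(draws)))
  }
  tibble::tibble(parameter = colnames(draws[[1]]) %||% paste0("p", seq_len(P)),
                 rhat = rhat, ess = ess,
                 flagged = !is.na(rhat) & rhat > 1.05)
}
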
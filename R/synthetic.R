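#' Truth configuration for synthetic multi-cohort data
#'
#' Describes the generating model of a synthetic study: cohort sizes, trait
#' means and variances, base item parameters, which items each cohort is
#' administered, a ledger of planted DIF (per-group parameter deviations),
#' and an optional twin structure. `simulate_cohorts()` draws responses
#' from exactly this model, so every downstream estimate can be compared
#' against known truth.
#'
#' @param groups Tibble with columns `group`, `n`, `mean`, `var`.
#' @param items Tibble with columns `item`, `alpha`, `beta1`, `beta2` (base
#'   parameters shared by all groups before DIF injection).
#' @param admin_mask Logical groups-by-items matrix; default all `TRUE`.
#' @param twin_frac Fraction of each group's persons arising as twin pairs
#'   (0 disables the family structure).
#' @param twin_cor Within-pair trait correlation when `twin_frac > 0`.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(groups, items, admin_mask = NULL, twin_frac = 0,
                         twin_cor = 0.5) {
  stopifnot(all(c("group", "n", "mean", "var") %in% names(groups)),
            all(c("item", "alpha", "beta1", "beta2") %in% names(items)),
            all(groups$n >= 1), all(groups$var > 0), all(items$alpha > 0),
            twin_frac >= 0, twin_frac <= 1)
  if (is.null(admin_mask)) {
    admin_mask <- matrix(TRUE, nrow(groups), nrow(items),
                         dimnames = list(groups$group, items$item))
  }
  stopifnot(identical(rownames(admin_mask), as.character(groups$group)),
            identical(colnames(admin_mask), as.character(items$item)))
  structure(list(groups = groups, items = items, admin = admin_mask,
                 dif = tibble::tibble(item = character(), group = character(),
                                      delta_beta1 = numeric(),
                                      delta_beta2 = numeric(),
                                      alpha_factor = numeric()),
                 twin_frac = twin_frac, twin_cor = twin_cor, C = 2L),
            class = "truth_config")
}

#' Default three-cohort scenarios
#'
#' Ready-made configurations emulating the structure of the three-cohort
#' harmonization study: unequal cohort sizes (1551 / 878 / 4501), a long
#' scale administered in two cohorts plus a short scale shared by all
#' three, 3-point items, and cohort trait means ordered TEDS > Raine >=
#' ABCD with gaps of roughly 0.4-0.6 SD. The `"adhd"` scenario has 11 long
#' plus 5 short items (TS = 32 over all items); `"anxdep"` has 31 plus 5,
#' with the third cohort administered only 4 of the 5 short items
#' (TS = 72 over all items). Item parameters are illustrative defaults for
#' behaviour-problem scales (symptoms rare, so thresholds sit above the
#' trait mean), not estimates of any published values.
#'
#' @param scale `"adhd"` or `"anxdep"`.
#' @return A [truth_config()].
#' @export
cohort_scenario <- function(scale = c("adhd", "anxdep")) {
  scale <- match.arg(scale)
  n_long <- if (scale == "adhd") 11 else 31
  n_short_admin <- if (scale == "adhd") 5 else 4
  items <- c(sprintf("cbcl%02d", seq_len(n_long)), sprintf("sdq%d", 1:5))
  K <- length(items)
  groups <- tibble::tibble(
    group = c("Raine", "ABCD", "TEDS"),
    n = c(1551, 878, 4501),
    mean = if (scale == "adhd") c(0, -0.40, 0.54) else c(0, 0, 0.58),
    var = c(1, 1, 1))
  # deterministic, mildly varied base parameters
  k <- seq_len(K)
  item_tbl <- tibble::tibble(
    item = items,
    alpha = 0.8 + 0.6 * (k %% 4) / 3,
    beta1 = 0.3 + 1.1 * ((k * 7) %% 10) / 10,
    beta2 = NA_real_)
  item_tbl$beta2 <- item_tbl$beta1 + 0.8 + 0.6 * ((k * 3) %% 5) / 5
  admin <- matrix(TRUE, 3, K, dimnames = list(groups$group, items))
  admin["TEDS", seq_len(n_long)] <- FALSE
  admin["TEDS", n_long + 1:5] <- c(rep(TRUE, n_short_admin),
                                   rep(FALSE, 5 - n_short_admin))
  truth_config(groups, item_tbl, admin)
}

#' Plant DIF into a truth configuration
#'
#' Adds a group-specific deviation for one item: threshold shifts
#' `delta_beta1`/`delta_beta2` and a multiplicative discrimination factor.
#' Other groups keep the base parameters; injections accumulate in the
#' configuration's DIF ledger.
#'
#' @param cfg A [truth_config()].
#' @param item Item label.
#' @param group Group label; the item must be administered there.
#' @param delta_beta1,delta_beta2 Additive threshold shifts.
#' @param alpha_factor Multiplicative discrimination change (`> 0`).
#' @return The updated `truth_config`.
#' @export
inject_dif <- function(cfg, item, group, delta_beta1 = 0, delta_beta2 = 0,
                       alpha_factor = 1) {
  stopifnot(inherits(cfg, "truth_config"), alpha_factor > 0)
  if (!item %in% cfg$items$item) stop("unknown item '", item, "'")
  if (!group %in% cfg$groups$group) stop("unknown group '", group, "'")
  if (!cfg$admin[group, item]) {
    stop("item '", item, "' is not administered in group '", group, "'")
  }
  cfg$dif <- dplyr::bind_rows(cfg$dif, tibble::tibble(
    item = item, group = group, delta_beta1 = delta_beta1,
    delta_beta2 = delta_beta2, alpha_factor = alpha_factor))
  cfg
}

true_param_table <- function(cfg) {
  out <- tidyr::expand_grid(group = cfg$groups$group, item = cfg$items$item)
  out <- dplyr::left_join(out, cfg$items, by = "item")
  out <- out[cfg$admin[cbind(out$group, out$item)], , drop = FALSE]
  if (nrow(cfg$dif) > 0) {
    for (r in seq_len(nrow(cfg$dif))) {
      sel <- out$group == cfg$dif$group[r] & out$item == cfg$dif$item[r]
      out$beta1[sel] <- out$beta1[sel] + cfg$dif$delta_beta1[r]
      out$beta2[sel] <- out$beta2[sel] + cfg$dif$delta_beta2[r]
      out$alpha[sel] <- out$alpha[sel] * cfg$dif$alpha_factor[r]
    }
  }
  out
}

#' Simulate multi-cohort GPCM responses with known truth
#'
#' Draws person traits from each cohort's normal distribution (optionally
#' with correlated twin pairs), then draws every administered response
#' category-wise from the GPCM probabilities under the group-specific true
#' parameters. Non-administered cells are missing by design. The returned
#' truth is reported *after* the identification rescaling (per-group mean
#' threshold 0, product of discriminations 1), matching the scale on which
#' the sampler reports estimates, so recovery comparisons are well-posed.
#'
#' @param cfg A [truth_config()].
#' @param seed Integer seed; the whole draw is reproducible.
#' @return A list: `data` (a [response_dataset()]) and `truth` (list with
#'   `theta` tibble, identified `params` table, identified `mu` and `sigma`
#'   per group, and the `config`).
#' @export
simulate_cohorts <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "truth_config"))
  set.seed(seed)
  J <- nrow(cfg$groups); items <- cfg$items$item; K <- length(items)

  theta <- list(); family <- list()
  for (j in seq_len(J)) {
    n <- cfg$groups$n[j]; mu <- cfg$groups$mean[j]
    sdv <- sqrt(cfg$groups$var[j])
    n_pairs <- floor(n * cfg$twin_frac / 2)
    n_single <- n - 2 * n_pairs
    th <- stats::rnorm(n_single, mu, sdv)
    fam <- sprintf("%s_s%05d", cfg$groups$group[j], seq_len(n_single))
    if (n_pairs > 0) {
      z1 <- stats::rnorm(n_pairs); z2 <- stats::rnorm(n_pairs)
      t1 <- mu + sdv * z1
      t2 <- mu + sdv * (cfg$twin_cor * z1 +
                          sqrt(1 - cfg$twin_cor^2) * z2)
      pf <- sprintf("%s_t%05d", cfg$groups$group[j], seq_len(n_pairs))
      th <- c(th, t1, t2)
      fam <- c(fam, pf, pf)
    }
    theta[[j]] <- th
    family[[j]] <- fam
  }
  grp <- rep(seq_len(J), cfg$groups$n)
  theta <- unlist(theta)
  family <- unlist(family)

  params <- true_param_table(cfg)
  arr <- params_to_arrays(params, cfg$groups$group, items, 2)
  # category draw via inverse CDF on the cellwise GPCM probabilities
  A <- arr$alpha[grp, , drop = FALSE]
  s1 <- A * (theta - arr$beta[[1]][grp, , drop = FALSE])
  s2 <- s1 + A * (theta - arr$beta[[2]][grp, , drop = FALSE])
  m <- pmax(s1, s2, 0)
  z <- exp(-m) + exp(s1 - m) + exp(s2 - m)
  p0 <- exp(-m) / z
  p1 <- exp(s1 - m) / z
  u <- matrix(stats::runif(length(theta) * K), length(theta), K)
  Y <- (u > p0) + (u > p0 + p1)
  storage.mode(Y) <- "integer"
  Y[is.na(A)] <- NA_integer_
  colnames(Y) <- items

  df <- tibble::as_tibble(Y)
  df$group <- cfg$groups$group[grp]
  df$family <- family
  ds <- response_dataset(df, items = items, group = "group",
                         family = "family", C = cfg$C,
                         admin_mask = cfg$admin,
                         groups = as.character(cfg$groups$group))

  admin <- !is.na(arr$alpha)
  id <- identify_arrays(arr$alpha, arr$beta, admin, theta, grp,
                        cfg$groups$mean, 1 / cfg$groups$var)
  truth <- list(
    theta = tibble::tibble(person = seq_along(theta),
                           group = factor(cfg$groups$group[grp],
                                          levels = cfg$groups$group),
                           theta = id$theta),
    params = arrays_to_params(id$alpha, id$beta, admin),
    mu = stats::setNames(id$mu, cfg$groups$group),
    sigma = stats::setNames(1 / id$tau, cfg$groups$group),
    config = cfg)
  list(data = ds, truth = truth)
}
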
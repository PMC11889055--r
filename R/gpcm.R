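#' GPCM category probabilities
#'
#' Probability of each response category `0..C` under the generalized
#' partial credit model. With discrimination `alpha` and thresholds
#' `betas = (beta_1, ..., beta_C)`, the category-`c` log weight is the
#' cumulative sum `sum_{v=1}^{c} alpha * (theta - beta_v)` (zero for
#' `c = 0`), normalized over all categories (divide-by-total). Computation
#' is done in log space with a log-sum-exp normalizer.
#'
#' @param theta Latent trait value(s); may be a vector.
#' @param alpha Discrimination, `> 0`.
#' @param betas Numeric vector of `C` thresholds.
#' @return A `length(theta)` by `C + 1` matrix of probabilities; each row
#'   sums to one.
#' @export
#' @examples
#' gpcm_prob(0, alpha = 1, betas = c(0, 0))  # uniform over 3 categories
gpcm_prob <- function(theta, alpha, betas) {
  stopifnot(length(alpha) == 1, alpha > 0, length(betas) >= 1)
  if (any(!is.finite(theta))) stop("theta must be finite")
  eta <- outer(theta, betas, function(t, b) alpha * (t - b))
  cs <- if (ncol(eta) > 1) t(apply(eta, 1, cumsum)) else eta
  s <- cbind(0, cs)
  m <- apply(s, 1, max)
  w <- exp(s - m)
  w / rowSums(w)
}

#' Expected item score under the GPCM
#'
#' The category-weighted mean `sum_c c * P(Y = c | theta)`; strictly
#' increasing in `theta` for positive discrimination, with range `(0, C)`.
#'
#' @inheritParams gpcm_prob
#' @return Numeric vector of expected scores, one per `theta`.
#' @export
expected_item_score <- function(theta, alpha, betas) {
  p <- gpcm_prob(theta, alpha, betas)
  drop(p %*% seq(0, length(betas)))
}

beta_cols <- function(params) {
  nm <- grep("^beta[0-9]+$", names(params), value = TRUE)
  nm[order(as.integer(sub("beta", "", nm)))]
}

params_for <- function(params, group, items) {
  sub <- params[params$group == group & params$item %in% items, , drop = FALSE]
  if (!setequal(sub$item, items) || nrow(sub) != length(items)) {
    missing <- setdiff(items, sub$item)
    stop("no parameters for item(s) ", paste(missing, collapse = ", "),
         " in group '", group, "' (not administered?)")
  }
  sub[match(items, sub$item), , drop = FALSE]
}

#' Test characteristic curve value
#'
#' Expected sum score over a set of items at trait value(s) `theta`, using
#' one group's item parameters: the functional relation between the latent
#' trait and the true score. Non-decreasing in `theta` when all
#' discriminations are positive, and bounded by `[0, C * length(items)]`.
#'
#' @param theta Latent trait value(s).
#' @param params Long parameter table with columns `group`, `item`, `alpha`,
#'   `beta1`, `beta2`, ... (one row per administered group-item pair).
#' @param group Group whose parameters to use.
#' @param items Items to sum over (must all be present for `group`).
#' @return Numeric vector of expected sum scores, one per `theta`.
#' @export
tcc <- function(theta, params, group, items) {
  if (length(items) == 0) return(rep(0, length(theta)))
  sub <- params_for(params, group, items)
  bc <- beta_cols(sub)
  out <- rep(0, length(theta))
  for (r in seq_len(nrow(sub))) {
    out <- out + expected_item_score(theta, sub$alpha[r],
                                     as.numeric(sub[r, bc]))
  }
  out
}

#' Observed-data GPCM log-likelihood
#'
#' Sum of log category probabilities over all observed responses on
#' administered items, evaluated in log space. Missing and
#' non-administered cells contribute zero; the result is additive over
#' persons and items.
#'
#' @param ds A [response_dataset()].
#' @param params Long parameter table as in [tcc()], covering every
#'   administered group-item pair.
#' @param theta Numeric vector of person trait values aligned to
#'   `ds$persons`.
#' @return A finite scalar log-likelihood.
#' @export
loglik_gpcm <- function(ds, params, theta) {
  stopifnot(length(theta) == nrow(ds$responses))
  arr <- params_to_arrays(params, group_levels(ds), item_names(ds), ds$C)
  sum(cell_loglik(theta, as.integer(ds$persons$group), arr$alpha,
                  arr$beta, ds$responses))
}

# params tibble -> list(alpha = J x K matrix, beta = C-list of J x K)
params_to_arrays <- function(params, groups, items, C) {
  bc <- beta_cols(params)
  stopifnot(length(bc) == C)
  J <- length(groups); K <- length(items)
  alpha <- matrix(NA_real_, J, K, dimnames = list(groups, items))
  beta <- lapply(seq_len(C), function(c) alpha)
  gi <- cbind(match(as.character(params$group), groups),
              match(as.character(params$item), items))
  keep <- !is.na(gi[, 1]) & !is.na(gi[, 2])  # rows for other groups/items
  gi <- gi[keep, , drop = FALSE]
  alpha[gi] <- params$alpha[keep]
  for (c in seq_len(C)) beta[[c]][gi] <- params[[bc[c]]][keep]
  list(alpha = alpha, beta = beta)
}

arrays_to_params <- function(alpha, beta, admin) {
  idx <- which(admin, arr.ind = TRUE)
  out <- tibble::tibble(group = rownames(admin)[idx[, 1]],
                        item = colnames(admin)[idx[, 2]],
                        alpha = alpha[idx])
  for (c in seq_along(beta)) out[[paste0("beta", c)]] <- beta[[c]][idx]
  ord <- order(match(out$group, rownames(admin)),
               match(out$item, colnames(admin)))
  out[ord, , drop = FALSE]
}

# Per-person log-likelihood; vectorized over an N x K response matrix.
# alpha / beta[[c]] are J x K; grp indexes persons into rows 1..J.
# Works for C = 2 (the fast path used throughout the sampler).
cell_loglik <- function(theta, grp, alpha, beta, Y) {
  lp <- cell_logprob(theta, grp, alpha, beta, Y)
  rowSums(lp, na.rm = TRUE)
}

cell_logprob <- function(theta, grp, alpha, beta, Y) {
  stopifnot(length(beta) == 2)
  A <- alpha[grp, , drop = FALSE]
  s1 <- A * (theta - beta[[1]][grp, , drop = FALSE])
  s2 <- s1 + A * (theta - beta[[2]][grp, , drop = FALSE])
  m <- pmax(s1, s2, 0)
  logZ <- m + log(exp(-m) + exp(s1 - m) + exp(s2 - m))
  lp <- -logZ
  i1 <- which(Y == 1L); i2 <- which(Y == 2L)
  lp[i1] <- lp[i1] + s1[i1]
  lp[i2] <- lp[i2] + s2[i2]
  lp[is.na(Y) | is.na(A)] <- NA_real_
  lp
}
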
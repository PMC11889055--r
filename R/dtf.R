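#' Observed mean difference between focal and reference groups
#'
#' `OMD = M_F - M_R`: the raw sum-score mean difference, which the DTF
#' decomposition splits into a measurement component (DTFR) and a true
#' latent-mean component (IMPACT).
#'
#' @param m_f,m_r Observed mean sum scores of the focal and reference
#'   groups on the shared items.
#' @return `m_f - m_r`.
#' @export
compute_omd <- function(m_f, m_r) m_f - m_r

#' DTF effect size
#'
#' `d_DTF = DTFR / SD_F`: the differential test functioning expressed in
#' focal-group sum-score standard-deviation units.
#'
#' @param dtfr DTFR value.
#' @param sd_f Focal group's observed sum-score SD; must be positive.
#' @return `dtfr / sd_f`.
#' @export
effect_size <- function(dtfr, sd_f) {
  if (any(sd_f <= 0)) stop("sd_f must be positive")
  dtfr / sd_f
}

#' IMPACT: the true-mean component of the observed difference
#'
#' `IMPACT = OMD - DTFR`: the part of the observed sum-score difference
#' attributable to a genuine latent-trait mean difference rather than to
#' differential test functioning, so that `OMD = DTFR + IMPACT` exactly.
#'
#' @param omd Observed mean difference (focal minus reference).
#' @param dtfr DTFR value.
#' @return `omd - dtfr`.
#' @export
compute_impact <- function(omd, dtfr) omd - dtfr

#' DTFR: expected TCC difference over the focal group
#'
#' For each focal-group person, the expected sum score on the shared items
#' is computed twice — once with the focal group's item parameters and once
#' with the reference group's — and DTFR is the mean of the differences
#' `TCC_F(theta_i) - TCC_R(theta_i)`. A positive value means the focal
#' parameters yield higher expected scores than the reference parameters
#' for the same people.
#'
#' @param theta_f Focal-group trait estimates (posterior means).
#' @param params Long parameter table as in [tcc()].
#' @param focal,reference Group labels.
#' @param items Items shared by both groups.
#' @return Scalar DTFR, in sum-score points.
#' @export
compute_dtfr <- function(theta_f, params, focal, reference, items) {
  if (length(theta_f) == 0) stop("empty focal group")
  mean(tcc(theta_f, params, focal, items) -
         tcc(theta_f, params, reference, items))
}

#' Test characteristic curve on a trait grid
#'
#' @param params Long parameter table as in [tcc()].
#' @param group Group whose parameters to use.
#' @param items Items to sum over.
#' @param theta_min,theta_max Grid endpoints; by convention the minimum and
#'   maximum observed trait estimates in the sample.
#' @param n_points Grid size (`>= 2`).
#' @return A tibble: `group`, `theta`, `expected`.
#' @export
tcc_curve <- function(params, group, items, theta_min, theta_max,
                      n_points = 101) {
  if (theta_min >= theta_max) stop("theta_min must be below theta_max")
  stopifnot(n_points >= 2)
  grid <- seq(theta_min, theta_max, length.out = n_points)
  expected <- tcc(grid, params, group, items)
  tibble::tibble(group = group, theta = grid, expected = expected)
}

#' Item-level DIF summary between two groups
#'
#' Posterior differences (focal minus reference) of each shared item's
#' discrimination and thresholds, with central credible intervals; an item
#' parameter is flagged when its interval excludes zero.
#'
#' @param fit An [fit_mggpcm()] result.
#' @param focal,reference Group labels.
#' @param conf_level Central interval coverage (default 0.95).
#' @return A tibble: `item`, `parameter`, `diff_mean`, `conf.low`,
#'   `conf.high`, `flagged`. Items not administered in both groups are
#'   excluded with a warning.
#' @export
dif_table <- function(fit, focal, reference, conf_level = 0.95) {
  stopifnot(inherits(fit, "mggpcm_fit"),
            all(c(focal, reference) %in% fit$groups))
  shared <- fit$items[fit$admin[focal, ] & fit$admin[reference, ]]
  if (length(shared) == 0) {
    warning("no shared items between '", focal, "' and '", reference, "'")
    return(tibble::tibble(item = character(), parameter = character(),
                          diff_mean = numeric(), conf.low = numeric(),
                          conf.high = numeric(), flagged = logical()))
  }
  dropped <- setdiff(fit$items[fit$admin[focal, ] | fit$admin[reference, ]],
                     shared)
  if (length(dropped) > 0) {
    warning("items not shared by both groups excluded: ",
            paste(dropped, collapse = ", "))
  }
  all_draws <- do.call(rbind, fit$draws)
  a <- (1 - conf_level) / 2
  out <- tidyr::expand_grid(item = shared,
                            parameter = c("alpha", "beta1", "beta2"))
  res <- purrr::pmap_dfr(out, function(item, parameter) {
    d <- all_draws[, paste0(parameter, "[", focal, ",", item, "]")] -
      all_draws[, paste0(parameter, "[", reference, ",", item, "]")]
    q <- stats::quantile(d, c(a, 1 - a))
    tibble::tibble(diff_mean = mean(d), conf.low = q[[1]], conf.high = q[[2]],
                   flagged = q[[1]] > 0 | q[[2]] < 0)
  })
  dplyr::bind_cols(out, res)
}

#' Scale-level DTF table for group pairs
#'
#' For each focal/reference pair, computes the observed sum-score statistics
#' on the items shared by the pair, DTFR over the focal group's trait
#' estimates, the `d_DTF` effect size, the observed mean difference and
#' IMPACT, plus paired TCC grids spanning the observed trait range — one
#' row per pair, mirroring the scale-level DTF report layout.
#'
#' @param fit An [fit_mggpcm()] result.
#' @param pairs A data frame with columns `focal` and `reference`; default
#'   all ordered pairs in group order.
#' @param items Optional item subset; per pair, intersected with the items
#'   administered to both groups.
#' @param n_points TCC grid size.
#' @return A tibble of class `dtf_result`: `focal`, `reference`, `n_items`,
#'   `ts`, `m_f`, `sd_f`, `m_r`, `sd_r`, `omd`, `dtfr`, `d_dtf`, `impact`,
#'   and a list-column `tcc` of per-pair curve tibbles.
#' @export
dtf_table <- function(fit, pairs = NULL, items = NULL, n_points = 101) {
  stopifnot(inherits(fit, "mggpcm_fit"))
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(focal = fit$groups, reference = fit$groups)
    pairs <- pairs[pairs$focal != pairs$reference, ]
    pairs <- pairs[match(pairs$focal, fit$groups) <
                     match(pairs$reference, fit$groups), ]
  }
  stopifnot(all(c("focal", "reference") %in% names(pairs)),
            all(pairs$focal != pairs$reference))
  params <- item_parameters(fit)
  scores <- score_persons(fit)
  out <- purrr::pmap_dfr(pairs[c("focal", "reference")],
                         function(focal, reference) {
    shared <- fit$items[fit$admin[focal, ] & fit$admin[reference, ]]
    if (!is.null(items)) shared <- intersect(shared, items)
    if (length(shared) == 0) stop("no shared items for pair ", focal, "-",
                                  reference)
    sf <- observed_sum_stats(fit$data, focal, shared)
    sr <- observed_sum_stats(fit$data, reference, shared)
    theta_f <- scores$theta_mean[scores$group == focal]
    dtfr <- compute_dtfr(theta_f, params, focal, reference, shared)
    omd <- compute_omd(sf$mean, sr$mean)
    rng <- range(scores$theta_mean)
    curves <- dplyr::bind_rows(
      tcc_curve(params, focal, shared, rng[1], rng[2], n_points),
      tcc_curve(params, reference, shared, rng[1], rng[2], n_points))
    tibble::tibble(focal = focal, reference = reference,
                   n_items = length(shared), ts = sf$ts,
                   m_f = sf$mean, sd_f = sf$sd, m_r = sr$mean, sd_r = sr$sd,
                   omd = omd, dtfr = dtfr,
                   d_dtf = effect_size(dtfr, sf$sd),
                   impact = compute_impact(omd, dtfr),
                   tcc = list(curves))
  })
  class(out) <- c("dtf_result", class(out))
  out
}

#' Plot paired test characteristic curves
#'
#' One line per group over a common trait grid, with the y-axis fixed to
#' the full theoretically possible score range `[0, TS]` so that small DTF
#' is seen in the context of the whole scale.
#'
#' @param curves A tibble with columns `group`, `theta`, `expected`
#'   (e.g. rows of [tcc_curve()] output bound together); at least two
#'   groups on an identical grid.
#' @param ts Maximum possible test score (y-axis upper limit).
#' @param out_path Optional file path (`.png`/`.svg`/`.pdf`); written via
#'   [ggplot2::ggsave()] when given.
#' @return The ggplot object, invisibly when `out_path` is given.
#' @export
plot_tcc_comparison <- function(curves, ts, out_path = NULL) {
  stopifnot(all(c("group", "theta", "expected") %in% names(curves)))
  grids <- split(curves$theta, curves$group)
  if (length(grids) < 2) stop("need curves for at least 2 groups")
  ref <- grids[[1]]
  if (!all(vapply(grids, function(g)
    length(g) == length(ref) && all(g == ref), TRUE))) {
    stop("curves must share a common theta grid")
  }
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$theta, y = .data$expected,
                                    colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, ts)) +
    ggplot2::labs(x = expression(theta), y = "Expected test score",
                  colour = "Cohort") +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = 7, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' @describeIn dtf_table Autoplot method: TCC comparison panels, one per
#'   group pair, y-axis fixed to `[0, TS]`.
#' @param object A `dtf_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.dtf_result <- function(object, ...) {
  df <- tidyr::unnest(
    dplyr::mutate(object, pair = paste(.data$focal, .data$reference,
                                       sep = " vs ")),
    "tcc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$expected,
                                   colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::expand_limits(y = c(0, max(object$ts))) +
    ggplot2::labs(x = expression(theta), y = "Expected test score",
                  colour = "Cohort") +
    ggplot2::theme_minimal()
}
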
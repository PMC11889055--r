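---
title: "Measurement-invariant harmonization with a multi-group GPCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement-invariant harmonization with a multi-group GPCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-cohort studies of child behaviour often hold overlapping but
unequal instruments: two cohorts answered a long checklist (e.g. 11 or 31
three-point items) *and* a short screening questionnaire, while a third
cohort only has 4–5 short-form items. Raw sum scores from different item
sets are not comparable, and even on shared items a score difference may
reflect either a true trait difference or differential item functioning
(DIF). `gpcmdtf` fits one latent-trait model across all cohorts, allows
every item parameter to differ by cohort, and then asks — at the item
level and at the scale level — whether those differences matter.

## Model

Responses $Y_{ik} \in \{0, \dots, C\}$ (here $C = 2$) follow a
generalized partial credit model with group-specific parameters. With
$\eta_{ck} = \tilde\alpha_{kj}(\theta_i - \tilde\beta_{ckj})$ for person
$i$ in group $j$,

$$P(Y_{ik} = c) =
  \frac{\exp\big(\sum_{v \le c} \eta_{vk}\big)}
       {\sum_{r=0}^{C}\exp\big(\sum_{v \le r} \eta_{vk}\big)},$$

with the empty sum for $c = 0$ equal to zero. A $C+1$-category item has
$C$ thresholds; each $\beta_c$ is the trait value where categories
$c - 1$ and $c$ are equally likely. We use the divide-by-total
(normalized) form throughout: it is the standard GPCM likelihood, and it
is the only reading under which the category probabilities form a
distribution.

Priors (all defaults of `prior_config()`):

* traits: $\theta_i \sim N(\mu_{\theta j}, 1/\tau_j)$ within group;
* group means: $\mu_{\theta j} \sim N(0, \text{precision } 0.1)$,
  i.e. variance 10 — diffuse enough to act as fixed effects;
* group precisions: $\tau_j \sim \Gamma(\text{shape } 1,
  \text{rate } 0.1)$ (prior mean precision 10). Gamma notation is
  ambiguous in parts of the measurement literature (BUGS-style
  $\Gamma(1, .1)$ is shape–rate); `prior_config(tau_gamma = "scale")`
  switches the reading if a user wants the other convention;
* item hierarchy: group-specific $\tilde\xi_{kj} = (\tilde\alpha_{kj},
  \tilde\beta_{1kj}, \tilde\beta_{2kj})$ are independent normal with
  variance 10 around general item parameters $\xi_k$ (the
  "quasi-fixed-effects" device: with only a handful of groups, random
  effects for groups are not estimable, so the prior is made diffuse);
  $\xi_k \sim N(\xi_0, \Sigma_\xi)$,
  $\xi_0 \sim N((1, 0, 0), I^{-1})$, and
  $\Sigma_\xi \sim \mathcal{IW}(I, d)$ with $d = 3$, the number of item
  parameters (one discrimination, two thresholds) — the smallest valid
  choice, hence the least informative. We centre the group-specific
  parameters on $\xi_k$ (the per-item means): centring them all on the
  grand mean $\xi_0$ would make the per-item layer inert.

## Identification

A latent scale has no intrinsic origin or unit: multiplying all of a
group's discriminations by $g$ and rescaling traits and thresholds
compensates exactly. We pin each group's scale by requiring, over the
items *administered to that group*,

* mean threshold $= 0$ (fixes the origin, so $\mu_{\theta j}$ are
  comparable), and
* product of discriminations $= 1$ (fixes the unit, so $\sigma_j$ are
  comparable).

`apply_identification()` implements the likelihood-preserving map
$\alpha' = \alpha/g$, $\beta' = g\beta - m$, $\theta' = g\theta - m$,
$\mu' = g\mu - m$, $\tau' = \tau/g^2$ with $g$ the geometric mean of the
group's discriminations and $m$ the post-scaling mean threshold. The
sampler applies it after every full scan, so *every stored draw is
identified* — constraint residuals on draws are below $10^{-8}$ by
construction, and tests verify the likelihood is untouched to
$10^{-10}$. For a cohort that saw only the short form, the constraints
use its administered items only; cross-cohort linking then flows through
the shared items and the hierarchy.

One consequence worth knowing: a *data-free* run with per-scan
identification would show the prior pushed through the rescaling map
(e.g. an inflated variance for $\mu_{\theta j}$). `fit_mggpcm(...,
identify = FALSE)` exposes the raw unconstrained chain; that is how the
prior-predictive test observes the $N(0, 10)$ prior for the group means
directly.

## Sampler

`fit_mggpcm()` is a vectorized Metropolis-within-Gibbs sampler:

* **Gibbs** for $\mu_{\theta j}$, $\tau_j$ (normal/gamma conjugacy given
  $\theta$), for $\xi_k$, $\xi_0$ (multivariate normal conjugacy) and
  $\Sigma_\xi$ (inverse-Wishart conjugacy);
* **random-walk Metropolis** elementwise for every $\theta_i$ and
  jointly for each administered $(\text{group}, \text{item})$ parameter
  triple. Discriminations are proposed on the log scale (with the
  Jacobian in the acceptance ratio), which keeps $\alpha > 0$ without
  truncation; the prior is still evaluated on the $\alpha$ scale.

Proposal scales adapt during burn-in (every 25 scans, nudged toward 30%
acceptance, clipped to safe ranges) and are frozen afterwards, so the
kept draws come from a fixed kernel. Initialization is deterministic and
data-driven: traits from standardized proportion scores, $\alpha = 1$,
thresholds from category-frequency logits, hyperparameters at prior
means. Given `mcmc_config(seed)`, a fit is bit-for-bit reproducible;
chain $c$ uses `seed + c - 1`.

All likelihood work is done in log space on an $N \times K$ matrix with
a log-sum-exp normalizer; missing and non-administered cells contribute
zero. Parameters for non-administered pairs are not sampled at all —
they are absent from the state rather than drifting from the prior.

Convergence is summarized by split-$\hat R$ and a Geyer
initial-monotone-sequence effective sample size
(`convergence_diagnostics()`, flag at $\hat R > 1.05$); both are
implemented in the package and validated against i.i.d., stuck-chain and
AR(1) cases (closed-form ESS $n(1-\rho)/(1+\rho)$).

## DIF and DTF

`dif_table()` reports, per shared item and parameter, the posterior
mean difference focal − reference and a central 95% interval; a
parameter is flagged when the interval excludes 0.

At the scale level (`dtf_table()`):

* $M_F, SD_F, M_R, SD_R$ are *observed sum-score* statistics on the
  pair's shared items (that is what published DTF tables report, so the
  effect size is in raw-score SD units);
* DTFR is the mean over focal-group persons of
  $TCC_F(\hat\theta_i) - TCC_R(\hat\theta_i)$, where $\hat\theta_i$ are
  posterior-mean traits. The sign convention is focal-minus-reference:
  positive DTFR means the focal group's parameters yield *higher*
  expected scores for the same people. Posterior means (rather than
  averaging over draws) are the package's default because the quantity
  is a plug-in functional of the trait point estimates; the TCC pieces
  are exposed (`tcc()`, `tcc_curve()`) for users who want to propagate
  posterior uncertainty;
* $d_{DTF} = DTFR / SD_F$, $OMD = M_F - M_R$, and
  $IMPACT = OMD - DTFR$, so $OMD = DTFR + IMPACT$ holds exactly —
  tested as an identity on every result.

Because the identification restrictions equalize average item difficulty
across groups by construction, DTFR should be near zero whenever groups
are allowed different trait means — observed mean differences are then
attributed to IMPACT. The test suite checks this null behaviour on 20
no-DIF replicates ($|DTFR| < 0.1 \cdot SD_F$ in at least 18).

TCC comparison plots span the observed trait range on the x-axis but fix
the y-axis to the *full theoretically possible score range* $[0, TS]$,
$TS = C \times \#\text{items}$: small DTF should look small relative to
the scale, and an axis zoomed to the observed scores would exaggerate
negligible differences.

## Synthetic cohorts

`cohort_scenario()` encodes the study design the package emulates: three
cohorts of 1551, 878 and 4501 persons; an ADHD-like scale of 11 long +
5 short items (max score 32) where the third cohort saw only the 5
short ones; and an anxiety/depression-like scale of 31 + 5 items (max
score 72) where the third cohort saw only 4 short items. Cohort trait
means are ordered third > first ≥ second with gaps of about 0.4–0.6 SD,
echoing the magnitudes of published IMPACT values; base item parameters
are a deterministic spread of discriminations 0.8–1.4 and positive
thresholds (behaviour problems are rare, so thresholds sit above the
trait mean). These defaults are illustrative study conditions, not
estimates of any cohort's published parameters (which are not available
numerically).

`simulate_cohorts()` draws traits (optionally as correlated twin pairs,
off by default), then categories from the GPCM cellwise inverse-CDF;
`inject_dif()` plants parameter deviations that are recorded in a ledger.
Truth is returned *after* the identification transform so recovery
comparisons are on the same scale the sampler reports.

What the generator does not emulate: non-ignorable missingness, age or
other covariate structure, rater effects, and any resemblance of the
base item parameters to the real instruments' estimates. Passing
recovery tests therefore demonstrate that the estimator works under the
model and design structure, not that the published cohort estimates are
reproduced.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to exercise the design while
keeping a full run comfortably interactive: recovery and null experiments
use 3 groups × 300 persons × 16 items with 200 burn-in / 800 kept
iterations and 20 replicates each (a single such fit takes a few seconds;
the sampler is a vectorized pure-R implementation, which at these sizes
makes compiled code unnecessary). The full published-style run
(1000 / 10000, cohort sizes in the thousands) is available through
`mcmc_config()` and `run_pipeline()`.

Other numerical choices: probabilities and likelihoods only in log
space; `pmax`-based log-sum-exp; threshold initial values clipped to
±2 logits; positive-definiteness of 3×3 covariances maintained by
symmetrization after each inverse-Wishart draw; proposal scales clipped
to [0.01, 5]. Degenerate inputs fail loudly: empty complete-case sets,
single-person SDs, inverted TCC grids, non-shared item pairs and
non-positive discriminations are all errors, not silent results.

## Pipeline order

`run_pipeline()` filters complete cases on the analyzed scale first and
then samples one person per family: per-scale sample sizes are reported
after both steps, and restricting the random selection to complete cases
avoids discarding a family whose selected member happens to be
incomplete while a complete sibling existed. Both removal counts are
logged, and the selection is seed-reproducible.

## Limitations

* DTFR is reported without an uncertainty band (the TCCs are plug-in
  curves at posterior-mean parameters).
* No Bayes-factor or posterior-predictive tests of DIF; decisions are
  effect-size based.
* One latent dimension; no graded-response or nominal alternatives.
* The generic category count $C$ is implemented but the package is
  exercised at $C = 2$ (3-point items).
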
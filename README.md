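# gpcmdtf

Harmonizing ordinal questionnaire scores across cohorts that did not all
answer the same instrument is a recurring problem in multi-cohort
epidemiology: two cohorts may have filled in a long behaviour checklist
plus a short screening questionnaire, while a third only has the short
form. `gpcmdtf` implements a Bayesian measurement-invariance workflow for
exactly this situation:

1. **Multi-group GPCM.** Responses coded 0/1/2 are modelled with a
   generalized partial credit model in which every cohort gets its own
   item parameters. For person *i* in group *j* and item *k*,

   P(Y = c | θ) ∝ exp( Σ_{v=1..c} α̃_kj (θ_i − β̃_vkj) ),  c = 0…C,

   with traits θ_i ~ N(μ_θj, 1/τ_j). Group-specific item parameters are
   quasi-fixed effects: they get diffuse normal priors (variance 10)
   centred on hierarchical general item parameters ξ_k, which in turn have
   a multivariate normal / inverse-Wishart hyperprior. The scale is pinned
   per group by two identification restrictions — mean threshold 0 and
   product of discriminations 1 over the items that group was administered
   — so cohort trait means and variances are comparable even when the
   item sets differ.

2. **DIF and DTF.** Item-level differential item functioning is
   summarized from posterior differences of each shared item's
   parameters. Scale-level differential *test* functioning is quantified
   the Stark way: with focal-group trait estimates θ_i, the test
   characteristic curve (TCC, expected sum score as a function of θ) is
   evaluated under both groups' item parameters, and

   DTFR = E[ TCC_F(θ_i) − TCC_R(θ_i) ],  d_DTF = DTFR / SD_F,
   OMD = M_F − M_R,  IMPACT = OMD − DTFR,

   so the observed mean difference decomposes exactly into a measurement
   part (DTFR) and a true latent-mean part (IMPACT).

3. **Synthetic cohorts.** Because such cohort data are typically
   restricted, the package ships a generator of multi-cohort GPCM data
   with known truth (unequal cohort sizes, short-form-only cohorts,
   planted DIF, optional twin pairs), which is how the whole pipeline is
   validated.

The package is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fits, `autoplot()` on DTF results.

## Worked example

```r
library(gpcmdtf)

# three synthetic cohorts: 300 persons each, 16 three-point items,
# trait means 0 / 0.4 / 1.0, one item with both thresholds +0.5 in G2
cfg <- truth_config(
  groups = tibble::tibble(group = c("G1", "G2", "G3"), n = 300,
                          mean = c(0, 0.4, 1.0), var = 1),
  items  = tibble::tibble(item = sprintf("it%02d", 1:16),
                          alpha = rep(c(0.8, 1.1, 1.4, 1.0), 4),
                          beta1 = rep(c(-0.5, 0, 0.5, 1.0), each = 4),
                          beta2 = rep(c(0.5, 1.0, 1.5, 2.0), each = 4)))
cfg <- inject_dif(cfg, "it01", "G2", delta_beta1 = 0.5, delta_beta2 = 0.5)
sim <- simulate_cohorts(cfg, seed = 42)

fit <- fit_mggpcm(sim$data, mcmc = mcmc_config(n_burn = 200, n_keep = 800,
                                               seed = 7))
dplyr::filter(tidy(fit), parameter == "mu")
#> # A tibble: 3 × ...
#>   term   parameter group   mean     sd
#> 1 mu[G1] mu        G1    -0.780 0.0657
#> 2 mu[G2] mu        G2    -0.458 0.0651
#> 3 mu[G3] mu        G3     0.181 0.0561
```

The estimated group means recover the planted contrasts (truth after
identification: −0.79 / −0.40 / 0.26): G2 sits ≈0.32 above G1 and G3
≈0.96 above G1, each within posterior uncertainty of the true gaps of
0.39 and 1.05. Scale-level DTF:

```r
dtf_table(fit, pairs = tibble::tibble(focal = "G1", reference = "G2"))
#>   focal reference n_items ts  m_f  sd_f  m_r  sd_r   omd   dtfr  d_dtf impact
#> 1 G1    G2             16 32 11.0  6.52 13.1  7.12 -2.15 -0.137 -0.021  -2.02
```

`omd = dtfr + impact` holds exactly: essentially all of the observed
2.15-point gap is a true trait difference (IMPACT −2.02), not measurement
bias (DTFR −0.14, d ≈ −0.02), which is what the identification
restrictions are designed to deliver. `autoplot()` on the result draws the paired TCCs with the y-axis
fixed to the full 0–32 score range.

`score_persons(fit)` returns the harmonized trait scores;
`dif_table(fit, "G2", "G1")` flags it01's shifted thresholds. The whole
workflow (simulate/read → filter → fit → DIF → DTF → figures) is also
available as one call, `run_pipeline()`, or from the shell via
`inst/cli/gpcmdtf.R`.

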
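---
title: "Benchmarking data leakage in connectome-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking data leakage in connectome-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Predictive models built on brain connectomes — subject-by-edge matrices of
Fisher-z connectivity values — are evaluated by cross-validation, and their
claimed performance is only meaningful if no information flows from the test
folds into training. In practice that boundary is breached in recurring ways:
edges are screened for phenotype correlation on the whole sample before
splitting; ComBat site harmonization or confound regression is fit on the
whole sample; the same subject appears twice; or relatives with correlated
brains and behavior are split across folds. `leakcv` implements a
gold-standard pipeline and explicitly leaky variants of each stage, so the
*performance cost or inflation of each breach can be measured* rather than
guessed, on data whose generative truth is known.

## The pipeline

The gold standard performs, strictly within each outer training partition:

1. **ComBat site harmonization.** Per feature $v$ and site $i$, the adjusted
   value is
   $x^{adj}_{ijv} = \frac{x_{ijv} - \hat\alpha_v - \gamma^{*}_{iv}}{\delta^{*}_{iv}} + \hat\alpha_v$
   with grand mean $\hat\alpha_v$, additive site effects $\gamma_{iv}$ and
   multiplicative site effects $\delta_{iv}$ estimated on standardized
   training data, by default with parametric empirical-Bayes shrinkage
   across features (normal prior for $\gamma$, moment-matched inverse-gamma
   for $\delta^2$). The frozen training parameters are applied to the test
   rows; a test-only site is an error, not a silent fallback.
2. **Covariate regression.** $\hat\beta = (C^\top C)^{-1} C^\top X$ on the
   training rows ($C$ = intercept, age, sex, motion; solved by QR), then
   $X - C\hat\beta$ on both partitions. When the phenotype *is* one of the
   covariates (predicting age), that covariate is excluded via
   `covariate_exclusions`.
3. **Feature selection.** The top 5% of edges by $|r|$ with the phenotype,
   computed on training rows only (ties break toward the smallest edge
   index; zero-variance edges rank last).
4. **Model fitting.** Ridge regression with a nested grid search over
   $\alpha = 10^{-3}, \ldots, 10^{3}$: plain inner 5-fold splits, features
   re-selected inside each inner training partition, inner predictions
   concatenated per grid value and scored by Pearson r, ties resolved toward
   the largest penalty. Alternatives: CPM (signed edge sums, univariate
   line) and radial-basis SVR with a cost grid.
5. **Splitting.** Family-aware k-fold: whole families are dealt, largest
   first, to the currently smallest fold, so relatives never straddle folds.

Each leaky variant changes exactly one stage: full-data selection, full-data
ComBat, full-data covariate regression, plain (family-ignorant) splits, or
verbatim duplication of a percentage of subjects before splitting.
Performance is always computed on predictions *concatenated across folds*
(one Pearson r and one $q^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$ per
iteration, never averaged per-fold metrics), and leakage effects are
reported as same-seed paired differences
$\Delta r = r_{leaky} - r_{gold}$, $\Delta q^2$ so split noise cancels.

```{r, eval = FALSE}
library(leakcv)
d <- generate_dataset(synthetic_config(seed = 7))
run_benchmark(d, pipeline_variants(), model_spec(), seed = 1)
```

## The synthetic generator

Real benchmark datasets in this area (ABCD, HBN, HCPD, PNC) are
restricted-access, so the package ships a generator that reproduces the
*structure* those analyses rely on, with known truth:

- a single standard-normal latent factor links brain and behavior: a
  configurable subset of edges loads on it, and the phenotype loading is
  calibrated so that the population $R^2$ of phenotype on the latent factor
  equals `effect_size` exactly (the recovery test regresses the phenotype on
  the stored latent scores and checks the bias);
- two-member (twin-like) families: a configurable fraction of subjects is
  paired, and pairs share a component of the latent factor, of the edge
  noise (a heritable connectome — this is the channel family leakage
  exploits), and of the phenotype noise, each with correlation `family_rho`;
  age is fully shared within a pair;
- sites impose per-site, per-edge additive shifts (SD `site_shift_sd`) and
  multiplicative scales (uniform on `site_scale_range`);
- covariates confound: age, sex and motion load on edges (per-edge Gaussian
  loadings with SD `covariate_effects$*$["x"]`) and on the phenotype
  (coefficients `["y"]`). Raw covariates are realistic (age in years uniform
  on 8–22, sex 0/1, motion log-normal around 0.13 mm) and standardized by
  their theoretical moments inside the generator so the variance bookkeeping
  is exact.

Defaults describe one fixed desk-scale population: 200 subjects, 100 nodes
(4950 edges), effect size 0.2, 2% signal edges, 25% of subjects in twin
pairs at $\rho = 0.6$, two mildly different sites (shift SD 0.1, scales
0.9–1.1), and an age confound (x = 0.3, y = 0.5). These were chosen once as
plausible analogs of a developmental cohort — multi-member families are a
minority, sites are well harmonized, age drives both connectivity and
behavior — and the direction-of-effect suite runs against them.

What the generator does **not** emulate: real marginal distributions of
connectivity, spatial autocorrelation on the cortex, larger sibships,
site-by-covariate interactions, or heavy-tailed noise. Passing tests
therefore show that each leakage mechanism behaves as documented under the
assumed structure, not that effect magnitudes transfer to any real cohort.

## Numerical and design choices

- **Edge order** is fixed package-wide: row-major strict upper triangle, so
  coefficient vectors are comparable across pipelines; any fixed convention
  would do since all analyses are order-invariant.
- **ComBat internals** use the mean-squared-deviation (divide-by-$n_i$) site
  scale and divide-by-$N$ pooled variance, which are mutually consistent:
  with shrinkage off the correction is exactly idempotent, per-site means
  equalize exactly, and the per-feature grand mean is preserved. Empirical
  Bayes is on by default (it is the standard estimator); the off mode exists
  because its algebra is exactly testable. Shrinkage is skipped for a site
  when the across-feature prior variance degenerates (fewer than 3
  features).
- **Stage order** within a fold is ComBat first, then covariate regression:
  site is an artifact of the measurement device, covariates are
  subject-level biology, so harmonization precedes residualization. Both
  stages are independent transforms (ComBat carries no covariate design).
  The opposite order is expressible by calling the correction functions
  directly.
- **Leaky feature selection** operates on the raw full-data features (per-
  fold corrections still run afterwards), keeping exactly one stage leaky
  per variant.
- **Hyperparameter aggregation** concatenates inner-fold predictions before
  scoring, matching the outer-loop convention, and breaks ties toward the
  strongest regularization for determinism. Whether features are selected
  once per outer training set or per inner fold is genuinely ambiguous in
  the field; re-selection per inner fold is the default because it keeps
  selection noise out of the penalty choice, and a fixed set can be passed
  via `fixed_features`.
- **Duplicated subjects** receive fresh singleton family ids, so
  family-aware splitting never reunites a duplicate with its source — the
  duplication stays a genuine leak.
- **Family subsampling** adds whole families in random order while the
  subject count stays at or below the target (the realized count is
  recorded), never overshooting.
- **Subnetwork size adjustment** divides the selected-edge count of each of
  the $G(G{+}1)/2$ network-pair bins by the bin's edge count; the rank
  correlations reported on these profiles use average ranks for ties.
  Degenerate inputs are surfaced, not patched: constant vectors make
  Pearson r `NA` with a warning, a constant phenotype makes $q^2$ an error,
  empty subnetworks are `NA` and dropped pairwise.

## Problem sizes used in the shipped checks

The direction-of-effect suite runs 20 paired split seeds per leakage type at
n = 200 subjects and 4950 edges; the qualitative ranking uses 10 seeds of
all variants on the default population; the subsampling sweep uses a
500-subject all-twin population at 780 edges, sizes 100 and 400, 10
resamples by family and 10 split iterations; effect-size recovery uses 50
populations of 2000 subjects. These sizes were chosen as the smallest at
which a pilot showed the qualitative effects are stable across seeds.

## Known limitations

Only size-2 families; linear single-factor signal (no interactions or
nonlinearity, so SVR has no structural advantage); no leave-one-site-out or
lockbox evaluation; no hyperparameter-selection or temporal leakage
variants; coefficient comparisons are defined for edge-linear models, with
CPM's sign-times-slope vector offered as a flagged convention and SVR
excluded.
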
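# leakcv

Quantifying what data leakage does to connectome-based predictive models.

## The problem

Brain-behavior prediction studies vectorize each subject's connectome into
an edge-feature vector, select phenotype-correlated edges, correct for site
and nuisance covariates, and fit a regularized model under k-fold
cross-validation. Every one of those stages can silently leak test-set
information into training: edges screened on the whole sample, ComBat or
covariate regression fit on the whole sample, duplicated subjects, or
relatives split across folds. `leakcv` is for methodologists and
neuroimaging analysts who want to *measure* the resulting inflation (or
deflation) instead of assuming it: it implements the gold-standard pipeline
and eleven variants that each break exactly one stage, scores them on
identical split seeds, and ships a synthetic connectome generator with
known ground truth so every effect is reproducible on a laptop.

## What it computes

For observed phenotype $y$ and test predictions $\hat y$ concatenated
across folds, each pipeline reports Pearson's $r$ and the cross-validation
$R^2$

$$q^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2},$$

which is negative when predictions are worse than predicting the mean.
Leakage effects are same-seed paired differences
$\Delta r = r_{leaky} - r_{gold}$ and $\Delta q^2$. The pipeline stages are
ComBat site harmonization
($x^{adj} = (x - \hat\alpha_v - \gamma^*_{iv})/\delta^*_{iv} + \hat\alpha_v$,
with empirical-Bayes shrinkage of the site parameters), OLS covariate
residualization ($X - C\hat\beta$ with $\hat\beta$ from training rows
only), top-5% edge selection by $|r|$, and ridge regression with a nested
grid search over $\alpha = 10^{-3..3}$ (CPM and RBF-SVR are alternative
model kinds). Model interpretation is compared via fold-averaged
coefficient correlations and size-adjusted selected-edge profiles over the
55 network-pair subnetworks of a 10-network parcellation.

## Worked example

```r
library(leakcv)

# a synthetic cohort: 200 subjects, 4950 edges, moderate brain-behavior
# signal, 25% twins, two mildly different sites, an age confound
d <- generate_dataset(synthetic_config(seed = 7))

specs <- list(gold_standard       = pipeline_spec(),
              leaky_selection     = pipeline_spec(feature_selection = "leaky"),
              leaky_covariates    = pipeline_spec(covariate_regression = "leaky"),
              family_leakage      = pipeline_spec(split = "plain"),
              subject_leakage_20  = pipeline_spec(subject_leakage_pct = 20))
run_benchmark(d, specs, model_spec(), seed = 1)
```

```
            pipeline           r         q2     delta_r    delta_q2
1      gold_standard  0.33022276  0.1047580  0.00000000  0.00000000
2    leaky_selection  0.58357401  0.2954093  0.25335125  0.19065133
3   leaky_covariates -0.02404942 -0.1604580 -0.35427219 -0.26521598
4     family_leakage  0.39468153  0.1456261  0.06445877  0.04086805
5 subject_leakage_20  0.48558620  0.2085769  0.15536344  0.10381887
```

Read it as: the honest pipeline earns r = 0.33 on this cohort; selecting
edges on the full sample inflates that by 0.25, duplicating 20% of
subjects by 0.16, and ignoring twin structure by 0.06, while fitting
covariate regression on the full sample *deflates* q2 by 0.27 — the same
qualitative ordering seen on real multi-site cohorts.

`delta_vs_gold()` pairs one leaky spec with the gold standard,
`run_iterations()` repeats a spec over many split seeds and reports
medians, `subsample_experiment()` maps leakage variability across sample
sizes, and `family_sweep()` traces the family-leakage effect as the
fraction of twins grows.

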
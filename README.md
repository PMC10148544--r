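# rarebayes

Bayesian shrinkage-prior prediction of rare binary adverse events from
many correlated baseline predictors.

## What this is for

Clinical cohorts that try to predict a *rare* outcome — here, whether a
smoker on cessation pharmacotherapy reports any neuropsychiatric adverse
event (NAE) during treatment, roughly a 10% outcome — from a wide baseline
battery (ordinal withdrawal/affect items, urge factor scores, a
nicotine-dependence index, demographics, treatment arm, metabolizer group)
sit at events-per-variable ratios of 1.5–3.3, where maximum-likelihood
logistic regression overfits and stepwise selection is unreliable.
`rarebayes` implements the Bayesian-regularization alternative end to end,
for biostatisticians building or stress-testing such prediction models.

The core model is a multilevel logistic regression with a site random
intercept,

```
y_i ~ Bernoulli(p_i),   logit(p_i) = b0 + u_site(i) + x_i' beta,
u_s ~ N(0, sigma_site^2),  sigma_site ~ half-t(4, 0, 2.5),  b0 ~ N(0, 100^2)
```

with one of three priors on the population-level coefficients:

* **horseshoe**: `beta_j ~ N(0, (lambda_j tau)^2)`, `lambda_j ~ half-t_df(0,1)`,
  `tau ~ half-Cauchy(0,1)`, df ∈ {1, 3, 5, 7};
* **laplace** (Bayesian LASSO): double-exponential via an exponential scale
  mixture of normals, df indexing a chi-square mixing family on the global
  rate;
* **vague**: `N(0, 100^2)`, the unregularized comparator.

Around that core: a synthetic multi-site cohort generator (Gaussian-copula
ordinal item batteries, tuned-intercept prevalence control), `caret`-based
predictor screening, dummy-coded standardized design matrices for an
item-level and a summary-score predictor set, outcome-preserving stratified
splits, an 18-model grid compared by WAIC and PSIS-LOO (both implemented
in-package and verified against exact leave-one-out refits), *hard
shrinkage* — variable selection by thresholding the posterior harm
probability P(OR > 1) with an AUROC-guided threshold sweep — and test-set
evaluation (AUROC with DeLong CI, Brier score, logistic recalibration,
decile calibration). Sampling is via JAGS (`rjags`, `glm` module) with all
scale priors in conjugate auxiliary-mixture form.

## Worked example

A down-scaled study run (one predictor set, two horseshoe cells plus the
vague comparator, 2 chains × 600; a few minutes on one core — defaults are
4 × 1000 for real use):

```r
library(rarebayes)
cfg <- default_pnat_config(seed = 1)    # n = 1203, 4 sites, 10% prevalence
study <- run_study(cfg, seed = 1,
                   grid = grid_configs(predictor_sets = "item",
                                       families = "horseshoe", dfs = c(1, 7)),
                   mcmc = mcmc_config(chains = 2, warmup = 600, sampling = 600))

study$epv
#> item
#>  1.6
study$grid$table[, c("id", "waic", "looic", "converged", "rank")]
#>                   id     waic    looic converged rank
#> 1 item:horseshoe:df7 577.0782 577.2008      TRUE    1
#> 2 item:horseshoe:df1 577.9848 578.1034     FALSE   NA
#> 3         item:vague 663.4492 664.4491     FALSE   NA
study$final$sweep
#>   threshold n_selected     auroc
#> 1      0.70          2 0.6075037
#> 2      0.65          5 0.5704742
#> 3      0.60          7 0.5696594
study$final$harm[, c("variable", "median_ror", "cri_low", "cri_high", "p_harm")]
#>              variable median_ror cri_low cri_high p_harm
#> 1 dreaming_nightmares      1.238   0.999     1.51 0.9712
#> 2              strong      0.848   0.663     1.03 0.0746
study$final$eval
#> <eval_report>
#>    AUROC: 0.61 (95% CI 0.51 - 0.71)
#>    Brier: 0.092 (null 0.094)
#>    Calibration intercept 0.78, slope 1.41
```

Reading this: the training set has 90 events against 58 design columns
(EPV 1.6). The horseshoe with 7 df wins the information-criterion
comparison; the vague model's WAIC is ~86 points worse and fails
convergence at these short chains — the regularized models are both better
and easier to sample. The threshold sweep keeps the 0.70 selection (two
variables, no measurable AUROC loss versus the 58-column model). The
retained "dreaming_nightmares" is one of the generator's true effects, at
a regularized odds ratio of 1.24 per SD with a 97% harm probability; at
10% prevalence even a true-signal model discriminates weakly (AUROC 0.61,
Brier barely below the null's 0.094), which is exactly the regime this
workflow is designed to make visible rather than hide.

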
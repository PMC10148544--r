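---
title: "Shrinkage-prior prediction of rare adverse events: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrinkage-prior prediction of rare adverse events: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multi-site trials of smoking-cessation pharmacotherapy collect dozens of
baseline measurements — ordinal withdrawal and affect item batteries,
smoking-urge factor scores, a nicotine-dependence index, demographics,
treatment arm, metabolizer group — and a rare composite outcome: whether a
participant reports any neuropsychiatric adverse event (NAE) during
treatment. At roughly 10% prevalence, a cohort of ~1200 yields ~120 events
against up to ~60 design columns, an events-per-variable (EPV) ratio of
1.5–3.3. Unpenalized logistic regression overfits badly in this regime and
stepwise selection compounds the damage. `rarebayes` implements the
alternative this package is built around: Bayesian regularization with
global–local shrinkage priors inside a multilevel logistic model, followed
by *hard shrinkage* — post-fit variable selection by thresholding posterior
sign probabilities — and a standard clinical-prediction evaluation triad.

## The model

For subject $i$ at site $s(i)$ with standardized predictor row $x_i$,

$$y_i \sim \mathrm{Bernoulli}(p_i), \qquad
\mathrm{logit}(p_i) = b_0 + u_{s(i)} + x_i^\top \beta,$$

with $u_s \sim N(0, \sigma_{site}^2)$,
$b_0 \sim N(0, 100^2)$, and
$\sigma_{site} \sim t^+_4(0, 2.5)$ (half-Student-t). The site intercepts
absorb between-center heterogeneity in event reporting. Three prior
families on $\beta$ define the model grid:

* **Horseshoe** — $\beta_j \mid \lambda_j, \tau \sim N(0, (\lambda_j\tau)^2)$,
  $\lambda_j \sim t^+_\nu(0, 1)$, $\tau \sim C^+(0, 1)$, with
  $\nu \in \{1, 3, 5, 7\}$; $\nu = 1$ is the classic half-Cauchy horseshoe.
  The global scale $\tau$ pulls everything toward zero; the heavy-tailed
  local scales let genuine signals escape.
* **Laplace (Bayesian LASSO)** — the double-exponential prior, represented
  as an exponential scale mixture of normals. The degrees-of-freedom grid
  enters through a $\chi^2_\nu$ mixing distribution on the global rate (the
  convention of the `brms` lasso prior); small $\nu$ puts substantial prior
  mass on near-zero rates, i.e. near-flat coefficient priors, which is
  exactly why the $\nu = 1$ cells mix badly (see *Sampling*, below).
* **Vague** — independent $N(0, 100^2)$, the unregularized comparator.

Crossing two predictor sets with the two shrinkage families at four df
values, plus one vague model per set, gives the 18-model grid of
`grid_configs()`.

### Two equivalent horseshoe parameterizations

One published way of writing the horseshoe carries the global scale inside
the local prior ($\beta_j \sim N(0, \lambda_j^2)$ with
$\lambda_j \sim C^+(0, \tau)$) rather than inside the coefficient prior.
At $\nu = 1$ the two parameterizations define the same marginal model. We
default to the standard form ($\lambda_j \sim t^+_\nu(0,1)$, scale
$\lambda_j\tau$ on $\beta_j$), which generalizes cleanly across the df
grid, and expose `literal_horseshoe = TRUE` in `prior_spec()` for the
other. The df grid is applied to the **local** scale distribution only;
the global scale stays $C^+(0,1)$. Applying df to the global (or both)
scales is a defensible alternative reading — we chose local-only because
it is the convention of the mainstream horseshoe implementations and the
only one that recovers the displayed half-Cauchy local prior at $\nu = 1$.

The Laplace hierarchy is often displayed with a Gaussian residual scale
$\sigma$; a Bernoulli likelihood has none, so `sigma_lasso` is fixed at 1.
The rate hyperparameter $\alpha$ defaults to 1 and is exposed in
`prior_spec()`.

## Sampling

Posterior draws come from JAGS (via `rjags`, with the `glm` module
loaded). All half-t and half-Cauchy scale priors are written as
inverse-gamma auxiliary mixtures
($x \sim t^+_\nu(0, A) \iff x^2 \mid a \sim \mathrm{IG}(\nu/2, \nu/a),\;
a \sim \mathrm{IG}(1/2, 1/A^2)$) and the Laplace as its exponential
normal-mixture, so every full conditional is conjugate and the `glm`
module can block-update the coefficient vector. This matters: with direct
half-Cauchy nodes the global scale moves by generic slice updates and its
Rhat stays above 1.1 at chain lengths where the auxiliary form is fully
mixed. A sampling test in the suite checks that the auxiliary mixture
reproduces the analytic half-t density.

Defaults are 4 chains × (1000 warmup + 1000 sampling); chain RNG streams
are derived from the seed, so identical inputs give identical draws.
Convergence is gated on split-Rhat (threshold 1.05) over all monitored
parameters plus effective sample sizes; JAGS has no divergent-transition
diagnostic, so the divergence field of a fit is identically zero and the
escalation path works purely through chain length: on failure,
`fit_with_escalation()` multiplies warmup and sampling by 2 (up to twice)
and refits. A model that still fails is returned flagged rather than
raised, because the grid must tolerate hard cells — in practice the
Laplace df = 1 cells and vague-prior fits on quasi-separated predictors
are the ones that fail, which mirrors how such grids behave generally.

## Preprocessing

`screen_predictors()` applies the conventional screen with `caret`:
zero-variance columns; near-zero-variance columns (frequency ratio > 19 =
95/5 **and** percent-unique < 10, the tool's defaults); one member of each
numeric pair with $|r| > 0.9$ (the member with the larger mean absolute
correlation); exact linear combinations. The correlation cutoff 0.9 is our
default, as no number is fixed by convention. Treatment, metabolizer group
and the baseline-NAE indicator are *design-protected*: a ~2% baseline-NAE
indicator trips the 95/5 rule on frequencies alone, but a variable kept by
design belongs in the model regardless of its marginal distribution.

`encode_design()` z-standardizes continuous *and* ordinal columns (ordinal
item scores are treated as numeric, matching per-unit odds-ratio
reporting), dummy-codes each k-level categorical against its reference
level, and adds metabolizer-by-treatment interaction columns. Two rosters
are built from the same cohort: the **summary set** (scale totals;
19 predictors / 26 columns with the default generator) and the **item
set** (individual items plus the two urges factors and the smoking
heaviness index; 51 predictors / 58 columns). The exact roster behind
those published counts cannot be uniquely reconstructed, so the default
generator's roster is chosen to reproduce them by construction: 14
demographic/clinical predictors plus the interaction in both sets, four
per-scale summaries (withdrawal total, positive and negative affect
totals, urges total) in the summary set, and 36 single columns in the item
set. One consequence of this bookkeeping is that the smoking-heaviness
index appears only in the item set. Standardization statistics default to
the full cohort — the conventional order of operations, which leaks a
little information from test to train — and `scale_on = "train"` is
available where that leak matters.

`split_cohort()` allocates events and non-events separately within each
site-by-metabolizer stratum using largest-remainder rounding, so event
rates in train and test agree to within one subject per stratum; strata
with fewer than two subjects go wholly to train with a warning.

## Model comparison and selection

`compute_waic()` and `compute_psis_loo()` are computed from the pointwise
log-likelihood matrix on the training set. The PSIS implementation fits a
generalized Pareto distribution (Zhang–Stephens posterior-mean estimator,
with the usual mild shape regularization) to the top 20% of importance
ratios per subject and replaces them by expected order statistics
truncated at the largest raw ratio; all-equal ratios fall back to plain
importance sampling with $\hat k = 0$. The suite cross-checks the whole
path against brute-force refit leave-one-out at n = 25 and checks WAIC on
a two-draw fixture by hand arithmetic. Ranking is by LOOIC with WAIC as
tie-break (the two agree on well-specified data; a consistency test
asserts this within combined standard errors), excluding non-converged
models.

`harm_probabilities()` reports, per design column, the posterior median
regularized odds ratio $e^{\mathrm{median}(\beta_j)}$, the 95% credible
interval, and the probability of harm $P(\mathrm{OR} > 1)$. Probabilities
≥ 0.8 or ≤ 0.2 are flagged as *important* — a reporting annotation,
deliberately distinct from the selection rule. `hard_shrinkage()` retains
variables with $P \ge t$ or $P \le 1 - t$, keeping categorical blocks
whole, and `threshold_sweep()` walks $t \in \{0.7, 0.65, 0.6\}$, refits
each candidate set with the winning model's own shrinkage prior (the
convention we adopt, since the final reported estimates are explicitly
regularized), and picks the smallest set whose test AUROC is within 0.01
of the full model's. The 0.01 tolerance operationalizes "retains the
discriminative ability"; no tighter value is conventionally fixed.

A property worth knowing when reading selection output: shrinkage priors
compress coefficient *magnitudes* far more than they compress *sign
probabilities*. On sparse synthetic data the horseshoe pulls noise medians
an order of magnitude below the vague-prior fit, yet the harm probability
of a noise column tracks the sample tilt of the data and lands outside a
(0.35, 0.65) band for roughly a quarter of noise columns at n = 1200 with
~120 events. Hard shrinkage at these thresholds therefore reliably keeps
every strong effect but admits some noise; the AUROC-guided sweep, not the
bare threshold, is what keeps the final model small.

## Evaluation

`posterior_predict()` propagates full posterior uncertainty (coefficients,
intercept, site effects) into subject-level probabilities; known-site mode
is the pipeline default since the split is within site, and marginal mode
draws fresh site effects for genuinely new sites. Posterior *means* of the
per-draw probabilities feed the metrics (the mean is the Bayes estimate
under squared error, which is what the Brier score measures; the
mean/median choice is not otherwise consequential here).
`evaluate_predictions()` reports AUROC with a DeLong 95% CI (checked
against `pROC` and against brute-force pair counting), the Brier score
with its null-model reference $q(1-q)$, a joint logistic recalibration
(intercept and slope; a weak-ridge Newton fallback handles separation, and
an intercept-given-slope-1 mode exists), and the decile calibration table.

## The synthetic generator

`default_pnat_config()` encodes the study conditions the package is
exercised under: n = 1203 subjects across 4 equally likely sites, site
random-intercept SD 0.3 (a moderate value on the logit scale — fitted but
not reported in this literature, and deliberately fixed rather than
revisited), 10% marginal prevalence, and sparse true effects: eight
nonzero per-SD log odds ratios between −0.14 (feeling proud, protective)
and +0.15 (nightmares), zero for treatment arms and everything else.
Ordinal items are generated by thresholding equicorrelated latent
Gaussians (a Gaussian copula; equicorrelation 0.4 within each scale block,
independence across blocks) with per-item category probabilities set to
reproduce published medians and quartiles (most withdrawal items at median
0 [0, 1]; positive affect around 3 [2, 4]; negative affect compressed at
1 [1, 2]); where no quartiles are available, probabilities are smooth
unimodal choices. The intercept is not a free parameter: `tune_intercept()`
root-finds $b_0$ by Monte Carlo (n = 10^5) so the marginal event rate hits
the target — tuning the intercept rather than rejection-sampling keeps the
effect sizes interpretable.

What the generator does **not** emulate: the real trial's joint predictor
distribution (only its margins and a single within-scale correlation
structure), longitudinal symptom trajectories (the outcome is generated
directly as one binary indicator, not via per-symptom severities), missing
data (the analysis sample is complete by construction), and any
nonlinearity or interactions beyond metabolizer-by-treatment. Passing
tests therefore demonstrate that the machinery is correct and that
recovery behaves as theory predicts under realistic margins and
multicollinearity — not that the trial's own numbers would be reproduced.

## Numerical choices and test-time problem sizes

Degenerate inputs are handled explicitly: constant predictions cannot be
recalibrated (error), all-tied predictions collapse the decile table to
one bin, single-class outcomes refuse an AUROC, empty hard-shrinkage
selections fall back to an intercept-only final model with a warning, and
an all-equal importance-ratio vector gets $\hat k = 0$. Ties in the split
allocation break deterministically (larger cells first, then cell order).

The test suite scales the study down so the full pipeline stays
exercised end to end: smoke grids run at n ≈ 250–500 with 2 chains of a
few hundred iterations, the recovery study at n = 1200 with 43 predictors
and 10 seeds at 2 × 600 iterations, and exact-LOO cross-checks at n = 25.
These sizes are the package's own test design; `mcmc_config()` defaults
remain 4 × (1000 + 1000) for real analyses.

## Known limitations

* The sampler is Gibbs-based; for much larger p or n a gradient-based
  backend would mix faster per draw. The escalation ladder compensates
  within this package's problem sizes.
* Harm-probability selection does not control the false-discovery rate;
  see the note under *Model comparison and selection*.
* The Laplace df = 1 cells frequently fail convergence by design of the
  prior; they are reported flagged, not silently dropped.
* Calibration metrics require predictions strictly inside (0, 1); the
  shrinkage models guarantee this, but user-supplied probabilities of 0
  or 1 are rejected.
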
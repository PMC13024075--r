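---
title: "Normative volumetric percentiles and AD classification: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative volumetric percentiles and AD classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volpct)
```

## The problem and the model

Raw regional brain volumes are hard to interpret at the individual level:
a 3500 mm^3 hippocampus may be unremarkable in an 85-year-old man and
alarming in a 55-year-old woman. The package addresses this by *normative
modelling*: for each of 95 segmented brain regions, the volume of a large
cognitively normal (CN) reference cohort is regressed on age and sex,

$$V_r = \beta_{0,r} + \beta_{1,r}\,\mathrm{Age} + \beta_{2,r}\,\mathrm{Sex} + \varepsilon_r,
\qquad \varepsilon_r \sim (0, \sigma_r^2),$$

with Sex coded 0 = female, 1 = male and $\sigma_r$ the residual standard
deviation. An individual's observed volume is standardized against the
model,

$$z_{r,i} = \frac{V_{r,i} - \hat V_{r,i}}{\sigma_r}, \qquad
P_{r,i} = 100\,\Phi(z_{r,i}),$$

giving a percentile $P_{r,i} \in (0, 100)$: the fraction of the age/sex-
adjusted reference population expected to have an equal or smaller volume.
The 95-element percentile profile $X_i = [P_{1,i}, \dots, P_{95,i}]$ is the
feature vector of a binary Alzheimer's disease (AD) vs CN classifier,

$$P(Y = \mathrm{AD} \mid X) = \frac{1}{1 + e^{-(\beta_0 + \sum_r \beta_r X_r)}},$$

fitted by ridge-penalized, class-weighted logistic regression.

Assumptions worth stating plainly: volume trends are linear in age with a
purely additive sex offset (no interaction, no quadratic aging, no
intracranial-volume normalization); residuals are Gaussian per region (the
percentile is parametric, $100\,\Phi(z)$, not an empirical rank); and the
reference cohort is genuinely disease-free. The percentile formula is the
operative definition throughout — where prose-level descriptions
("proportion of the reference population ...") and the formula could
diverge for non-Gaussian residuals, the formula wins.

## Fitting details and numerical choices

* **Normative fit** — per-region ordinary least squares via `stats::lm`
  on the design `[1, age, sex]`. `sigma_r` uses the unbiased `n - 3`
  denominator. Rank-deficient designs (single sex, constant age, n < 4)
  are hard errors, as is any region whose residual SD falls below a floor
  (default `1e-8` mm^3): a degenerate region would make every downstream
  z-score meaningless. Percentiles are kept at full precision — the
  classifier consumes them as continuous features, so rounding to integer
  percentiles would discard information.

* **Classifier objective** — `train_logistic()` minimizes
  $$\frac{1}{2C}\lVert\beta\rVert_2^2 + \sum_i w_{c(i)}\,
  \log\!\left(1 + e^{-y_i(\beta_0 + x_i^\top\beta)}\right), \quad y_i \in \{-1, +1\},$$
  with the intercept unpenalized and $C = 1$ by default. This is the
  dominant convention for a regularization strength named "C" (penalty
  weight $1/C$, per-sample loss unnormalized). Class weights
  $w_c = N/(2N_c)$ multiply each sample's loss term, so each class
  contributes half the effective weight regardless of imbalance
  ($\sum_c w_c N_c = N$ identically). The fit is damped Newton on the
  exact objective — the problem is strictly convex, 96 parameters, and
  converges to a gradient max-norm below `1e-6` (configurable) in a
  handful of iterations; a step is halved until the objective decreases.
  Tests verify the optimum against an independent generic minimizer of
  the same objective and against glmnet's ridge logistic path point
  ($\lambda = 1/(nC)$, weights already summing to $n$).

* **Standardization protocol** — feature means/SDs (`n - 1` denominator)
  are computed on the *training split only* and frozen into the model
  object; validation, test and external cohorts are transformed with the
  training statistics. Constant training features are an error, named by
  region.

* **Split convention** — `stratified_split()` allocates 60/20/20
  sequentially: the training split takes `floor(0.6 N)` subjects overall;
  within each split, per-class counts follow largest-remainder rounding of
  the remaining class pool, with ties broken toward the earlier class in
  lexicographic order (AD before CN); the last split takes the remainder.
  For 873 subjects (183 AD / 690 CN) this gives 523/175/175 with
  110/37/36 AD — the canonical counts for this protocol. Membership
  within a class is randomized by the seed; the counts are deterministic.

* **Decision rule** — labels at threshold 0.5, with a probability exactly
  at the threshold classified AD. The tie direction is arbitrary but
  documented and tested; with continuous features, exact ties have
  measure zero.

* **ROC/AUC** — thresholds at every distinct score plus a sentinel; AUC
  by trapezoid, which for this construction equals the Mann–Whitney pair
  statistic with ties credited 1/2. The equality is asserted against
  exhaustive pair enumeration in tests.

* **Cross-validation** — stratified 5-fold within the training split,
  dealing each class round-robin after a seeded shuffle (fold sizes and
  per-fold class counts differ by at most 1). Every fold refits the full
  protocol — scaler, class weights, classifier — on the other folds; the
  fold SD uses the `k - 1` denominator.

* **Undefined metrics** — any metric with a zero denominator (e.g.
  precision with no positive predictions) is reported as `NA`
  ("undefined"), never silently 0.

## The synthetic cohort generator

Real reference and diagnostic cohorts of this kind are access-restricted,
so the package ships a generator that draws cohorts from exactly the
generative model the normative stage assumes. That circularity is the
point: it makes the pipeline's statistical properties testable
(probability-integral-transform uniformity of reference percentiles,
OLS parameter recovery, chance-level AUC under the null) without any
private data.

Defaults are fixed once, as the package's study conditions:

* **Demographics** (`adni_like_config()`): a reference cohort of 1833 CN
  subjects aged 21–90 (47.1% female, uniform ages); an internal
  diagnostic cohort of 690 CN (ages truncated-normal 71.8 ± 7.0 within
  50–90, 58.4% female) and 183 AD (77.3 ± 6.1, 46.4% female). The
  external cohort (`korean_like_config()`) has 36 AD / 36 CN, ages near
  68, near-balanced sex. Uniform ages are the reference default because
  they condition the regression well across the whole range; diagnostic
  cohorts use the truncated-normal mode to mirror realistic case-mix
  demographics.

* **Region parameters** (`region_gen_defaults()`): baseline volumes by
  structure class (e.g. ~4000 mm^3 hippocampus, ~1600 mm^3 amygdala,
  ~240 cm^3 cerebral white matter, small CSF spaces); parenchymal regions
  lose 0.15% of baseline per year while ventricles/CSF spaces gain 1.5%
  per year; males +4% of baseline; residual SD 12% of baseline. These are
  round, literature-plausible magnitudes — the pipeline's behaviour
  depends on effect sizes in $\sigma$ units, not on the absolute scales.

* **Disease effects**: expressed in $\sigma$ units (scale-free, directly
  interpretable as percentile shifts). Defaults: $-1.5\sigma$ for the
  hippocampi, amygdalae and entorhinal cortices; $+1.5\sigma$ for the
  inferior lateral ventricles, lateral ventricles, CSF and WM
  hypointensities; 0 for the remaining 83 regions. The external cohort
  uses the same pattern scaled to $\pm 1.0\sigma$, emulating a
  milder/more heterogeneous disease profile in an independently recruited
  population — this reproduces the qualitative phenomenon of preserved
  AUC with reduced sensitivity at the 0.5 threshold, without claiming to
  reproduce any cohort quantitatively.

* **Correlation structure**: residuals are independent across regions by
  default, because the per-region normative model makes no claim about
  covariance. An optional shared per-subject latent factor
  (`shared_factor_sd`) adds a crude "global atrophy" correlation for
  robustness experiments.

What the generator does **not** emulate: scanner/site batch effects,
non-linear aging, heavy-tailed or skewed residuals, region–region
covariance beyond the single latent factor, MCI phenotypes, longitudinal
trajectories, segmentation failures. Passing tests on synthetic cohorts
therefore demonstrate the *statistical machinery* is correct and
leakage-free; they do not demonstrate clinical performance on real data —
with features drawn from the assumed model, discrimination is
optimistic relative to real cohorts.

## Experiment sizes and determinism

`run_experiment()` executes the whole protocol from one config: simulate
(or load) cohorts, fit the normative model on the reference only, score
percentiles, split 60/20/20, fit scaler + weights + classifier on the
training split only, 5-fold CV, and evaluate on internal validation,
held-out test and the external cohort with no retraining. The default
simulated experiment (1833 + 873 + 72 subjects x 95 regions) runs in
under a second; the test suite's property checks use n = 5000 draws where
a distributional assertion needs them. All randomness flows from a single
integer seed (stage seeds are derived by fixed offsets), so a config plus
seed reproduces every number bit-identically; persisted artifacts
(models, percentile tables, per-subject probabilities) allow every
reported metric to be recomputed from disk.

## Known limitations

* The linear age model will miscalibrate percentiles at the extremes of
  age if real trajectories are non-linear; quantile-regression or
  GAMLSS-style normative models are deliberately out of scope.
* Percentiles are parametric-Gaussian; skewed regions (e.g. ventricles in
  real data) would need a transformation before the model fits well.
* Coefficient rankings from ridge logistic regression are stable but not
  causal; correlated regions share credit, which is why
  traditionally atrophic regions can carry negative weights in a
  multivariate model whose positive ventricular coefficients already
  encode global atrophy.
* The split convention reproduces one specific published count pattern;
  other rounding rules are equally defensible but would shift one or two
  subjects between splits.
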
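---
title: "Models and methods: ordinal outcome and thrombectomy benefit prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ordinal outcome and thrombectomy benefit prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evtpredict)
```

## The problem

Endovascular thrombectomy (EVT) has a large average benefit for anterior
large-vessel-occlusion stroke, but individual benefit varies widely and
roughly half of treated patients do not reach functional independence.
`evtpredict` implements the full development-and-validation workflow for
prediction models that address two questions at the point of treatment
decision:

1. *Prognosis*: what is this patient's probability of a good 90-day
   functional outcome (modified Rankin Scale, mRS 0–2)?
2. *Benefit*: how much does EVT change that probability for this
   particular patient?

Three model specifications are shipped: a CT-feature-only model (ASPECTS,
occlusion location, collateral score, white-matter-lesion volume, brain
parenchymal fraction, intracranial carotid calcification subtype), its
extension with age and baseline NIHSS, and a reference clinical+imaging
specification re-fit to the cohort at hand.

## The outcome model

The 90-day mRS (0 best, 6 dead) is modeled on its full ordinal scale with
a proportional-odds (common odds ratio) cumulative-logit model,

$$
P(\mathrm{mRS} \le k \mid x) = \operatorname{expit}(\alpha_k + x^\top\beta),
\qquad k = 0,\dots,5 .
$$

The orientation is fixed so that $e^{\beta_j} > 1$ means a *better*
outcome; this matches how common odds ratios are conventionally printed
for these trials and is asserted throughout the package. The probability
of good outcome is read off the same fit as
$P(\mathrm{mRS}\le 2) = \operatorname{expit}(\alpha_2 + x^\top\beta)$, and
individual treatment benefit is the counterfactual contrast

$$
\hat\tau(x) = P(\mathrm{mRS}\le 2 \mid x, \mathrm{EVT}=1)
            - P(\mathrm{mRS}\le 2 \mid x, \mathrm{EVT}=0),
$$

evaluated by setting the treatment indicator (and its interaction
columns) to 1 and then 0 with all other covariates fixed.

**Fitting.** `fit_proportional_odds()` maximizes the likelihood by
Newton–Raphson with analytic gradient and Hessian. The cumulative-logit
log-likelihood is concave in $(\alpha, \beta)$; intercept monotonicity
(which guarantees nondecreasing cumulative probabilities for every
patient) is preserved by the step-halving line search, because an
intercept crossing annihilates a category probability and blows up the
objective. Convergence is declared at gradient norm $< 10^{-6}$;
standard errors come from the inverse observed information at the
optimum. A two-level outcome reduces the model exactly to binary
logistic regression, which the tests exploit as an independent oracle
(along with a second, independently implemented proportional-odds
routine).

**Treatment-effect modification.** The EVT-by-collateral interaction is
always included (a design inherited from how such models are built for
these trials); further interactions are deliberately not selected
data-driven, since that is a known overfitting hazard for heterogeneous
treatment effect estimation. During backward elimination
(`backward_eliminate()`, joint Wald test per variable block, removal
threshold p > 0.20), the treatment term and any variable interacted with
it are protected.

## Restricted cubic splines

Continuous predictors with curved effects (BPF, and in the extended and
reference models age, systolic blood pressure, glucose) enter through a
restricted ("natural") cubic spline: a truncated-power basis with
linearity enforced beyond the boundary knots, normalized by the squared
boundary-knot span so coefficients stay on the variable's own scale.
Three knots are used everywhere, because the models are summarized with
a single inflection value per variable: the middle knot is pinned at
that value (BPF 80%, age 65 years, SBP 130 mmHg, glucose 120 mg/dL) and
the outer knots sit at the 10th and 90th percentiles of the *training*
sample. Knots are resolved on the training data at fit time and travel
with the fitted model, so held-out predictions reuse the training
placement. `summarize_effects()` reports spline effects the way such
models are conventionally printed: one odds ratio per unit change below
the inflection value and one above, computed as exponentiated chord
slopes of the fitted curve with delta-method intervals.

## Validation design

**Internal–external cross-validation (IECV).** With a pooled multi-trial
cohort the natural validation unit is the trial: `iecv()` leaves one
study out, refits everything (knot placement included) on the remaining
studies, and evaluates on the held-out study — repeated until each trial
has been left out once, giving one performance estimate per trial. Fold
estimates are pooled by DerSimonian–Laird random-effects meta-analysis
(`pool_random_effects()`), which also reports the between-study variance
$\tau^2$; heterogeneity across folds is expected, since trials differ in
case-mix and baseline outcome probability.

**Discrimination.** Harrell's C for the ordinal outcome uses the model's
linear predictor as the ranking score (monotone in every exceedance
probability under proportional odds); a binary C-statistic is computed
for the good-outcome probability. Both are computed by a sorted-group
counting algorithm (exactly equal to exhaustive pair enumeration, which
the tests verify) with ties credited 0.5 and jackknife standard errors.
The jackknife is used for per-fold SEs, rather than a bootstrap, so the
metric layer stays deterministic and the only resampling in the pipeline
is the explicit model-comparison bootstrap.

**Calibration.** The calibration slope is the coefficient of
$\operatorname{logit}(\hat p)$ in a logistic recalibration model; the
intercept is estimated with $\operatorname{logit}(\hat p)$ as a fixed
offset (slope held at 1). That offset convention is a package decision —
the alternative (intercept from the free-slope model) is not what
standard recalibration frameworks report. Probabilities are clipped to
$[10^{-6}, 1-10^{-6}]$ before the logit.

**Benefit metrics.** Individual benefit is unobservable, so observed
benefit is defined on treated–control pairs matched 1:1 without
replacement on baseline covariates: the difference of the two patients'
good-outcome indicators, in $\{-1, 0, 1\}$. `match_pairs()` uses greedy
nearest-neighbour assignment on Mahalanobis distance (standardized
continuous plus dummy-coded categorical covariates), ties broken by a
seeded shuffle; matching on predicted benefit is available as a
sensitivity option. Matching is performed within trial by default,
because randomization guarantees exchangeability of arms only within a
trial. Greedy rather than optimal assignment is a deliberate choice: it
is deterministic, near-optimal for this diagnostic purpose, and cheap.
The C-for-benefit is then the concordance, over pairs of matched pairs
with unequal observed benefit, between observed and predicted pair
benefit (predicted pair benefit = mean of the two patients' predicted
benefits); mean benefit calibration is mean observed minus mean
predicted pair benefit, so positive values mean under-predicted benefit.

**Model comparison.** `compare_models_bootstrap()` reports the
difference in C (or C-for-benefit) between two models on the same
out-of-fold predictions, with a percentile 95% CI from 500 resamples of
patients (or matched pairs) drawn with replacement, stratified by trial
to preserve case-mix. `added_value_analysis()` adds candidate variables
one at a time to a base specification, screens by full-data likelihood
ratio test at p < 0.05, and re-validates only the variables that pass.

**Missing data.** Baseline covariates are imputed by chained equations
(`impute_missing()`, default m = 5): stochastic linear-regression draws
for continuous variables, logistic draws for binaries, multinomial draws
for unordered categoricals, and rounded, range-clipped draws for bounded
integer scores; the outcome and treatment arm are included as predictors
in every imputation model, and 10 cycles are run. Fold metrics are
combined across imputations per fold with a Rubin-style total variance
(mean within-imputation variance plus $(1+1/m)$ times the
between-imputation variance) before meta-analytic pooling. Variable
selection is performed once on the full development data before IECV;
folds re-estimate coefficients only. Per-fold selection is a defensible
alternative, but the shipped specifications have fixed term lists, and a
fixed list is what a reference model re-fit requires.

## The synthetic cohort generator

Patient-level data from the underlying trial pool are not public, so the
generator (`generate_cohort()`, `default_hermes_config()`) emulates the
study conditions end-to-end and gives every downstream stage a known
truth:

* **Seven trials, 1391 patients** (450/240/60/150/160/280/51, roughly
  proportional to the constituent trials' enrolments), 1:1 treatment
  allocation.
* **Covariate distributions** matched to the published baseline table:
  age ~67 ± 13 years, NIHSS ~17, ASPECTS concentrated at 8–10,
  collateral mostly grades 2–3, occlusion 21/71/7% ICA/M1/M2, BPF
  ~80.4 ± 2.6%, WML and old-infarct volumes as zero-inflated log-normals
  (≈15% and ≈77% exact zeros). Brain frailty tracks age (higher WML and
  old-infarct burden, lower BPF, more medial calcification with
  advancing age), mirroring the reported age gradients.
* **Outcomes** drawn from the proportional-odds process
  $P(\mathrm{mRS}\le k)=\operatorname{expit}(\alpha_k+\eta)$ whose
  coefficients default to the natural logs of the published common odds
  ratios (imaging effects from the CT-feature model column, age/NIHSS
  from the extended column, remaining clinical effects from the
  reference column). Spline effects are specified as chord slopes below
  and above the published inflection points and converted to basis
  coefficients, so the generating curve reproduces exactly the printed
  two-segment summaries. The EVT-by-collateral interaction is never
  printed; its default is ln(1.15) per collateral point — a mild
  positive modification consistent with the term's inclusion — and it is
  overridable.
* **Between-trial heterogeneity** enters through case-mix location
  shifts and a per-trial shift of the intercept vector (baseline outcome
  probability), not through trial-specific coefficient effects: the fold
  heterogeneity seen in this design is chiefly attributed to case-mix
  and baseline probability differences.
* **Intercepts** are calibrated (`calibrate_intercepts()`) so a large
  simulated draw reproduces the published control-arm good-outcome
  proportion (27.9%); the treated arm then lands near its published
  45.6% because the treatment coefficients govern it. The 7-category
  spacing around that anchor is a package choice (the full per-arm mRS
  distributions are not published); the shipped default intercepts are
  the calibrated values.
* **Missingness** is MCAR per covariate (defaults of 1–5% on the imaging
  and laboratory variables), applied after outcome generation.

What the generator deliberately does *not* emulate: images or
segmentation outputs (imaging features enter only as tabular
covariates), per-trial inclusion-criteria rule engines, informative
missingness, and measurement error in the CT features. Tests passing on
this generator therefore demonstrate the *statistical machinery* —
estimation, validation design, benefit metrics — under a faithful
proportional-odds world; they cannot certify performance on real trial
data, where effects are not exactly proportional-odds and missingness is
not MCAR.

## Numerical choices and degenerate inputs

* Category probabilities below `1e-300` are floored inside the
  likelihood; probabilities are clipped at `1e-6` before logits in
  calibration.
* Coefficients with $|\hat\beta| > 15$ trigger a separation warning and
  are flagged on the fit object.
* A singular information matrix falls back to an eigenvalue
  pseudo-inverse with a warning; a singular Mahalanobis covariance is an
  error suggesting more ridge regularization (default `1e-8` on the
  standardized scale).
* Concordance is an error when all observed values are equal; per-fold
  undefined metrics are recorded as `NA`, excluded from pooling, and
  warned about — never silently imputed.
* Quantile bins use equal counts with the last bin absorbing remainders;
  constant predictions in a calibration curve warn about single-bin
  behavior.
* Tie-breaking in matching is randomized under the caller's seed; every
  stochastic routine takes an explicit seed and restores the caller's
  RNG state.

## Problem sizes used by the shipped checks

The test-suite simulations use cohorts of 300–70,000 patients: parameter
recovery averages 10 replicates at n = 10,000 (the EVT term and its
collateral interaction are nearly collinear, so single-draw noise on
each alone reaches the size of the recovery tolerance), Wald coverage
uses 200 replicates at n = 2,000, the type-I-error check uses 500
simulations at n = 1,000, and generator fidelity uses a 50,000-patient
draw. The acceptance script runs the full pipeline at the study scale
(1391 patients, m = 5 imputations, B = 500 bootstrap resamples).

## Known limitations

* The proportional-odds assumption is imposed, not tested; no
  partial-proportional-odds or random-effects extensions are provided.
* The reference specification re-fits the reference model's *term list*
  to the cohort at hand; it does not reproduce the original published
  coefficients.
* Benefit metrics depend on the matching design; with weak effect
  modification the C-for-benefit of a correct model sits only modestly
  above 0.5, and matched-pair observed benefit is intrinsically noisy
  (a difference of two Bernoulli draws).
* Greedy matching is near-optimal, not optimal; no inverse-probability
  or regression-based observed-benefit alternatives are implemented.
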
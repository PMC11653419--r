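---
title: "Methods: signal detection analysis of yes/no treatment decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal detection analysis of yes/no treatment decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdtreat)
```

## The question

A clinician or patient makes a binary treatment decision — for example,
whether to start a device evaluation period, or whether to take up
counseling — before the treatment outcome is known. Retrospectively,
every participant can be labelled by whether treatment *would have*
helped: population **S2** (treatment beneficial) versus **S1** (not
beneficial). Viewing the yes/no decision as a detector of S2 membership
turns decision quality into a signal detection problem: how well does a
continuous *driver* available at decision time (hearing loss in dB HL, a
baseline handicap score) separate the two populations, and where does
the implicit decision criterion sit relative to the criterion that would
maximize benefit?

## Outcome labelling

`label_outcome()` assigns S2 when the post-treatment handicap score
improves by more than a minimal clinically important difference (MCID):

\[ \text{S2} \iff \mathrm{THI}_{\text{post}} - \mathrm{THI}_{\text{base}} < -\mathrm{MCID}, \]

with MCID = 7 by default (strict inequality; a change of exactly −7
stays S1). Labelling requires complete scores, which is why the
imputation chain runs first.

## The unequal-variance logistic model

Each population's driver distribution is modelled as a logistic
distribution: S1 ~ Logistic(μ₁, s₁), S2 ~ Logistic(μ₂, s₂), with the
scales free to differ. The model is fit through the equivalent
logistic-regression parameterization θ₁ = −μ/s, θ₂ = 1/s, so that

\[ P(\text{yes} \mid x) = \mathrm{logit}^{-1}(\theta_1 + \theta_2 x) \]

within each population is exactly the CDF of that population's component.
A criterion *c* on the driver axis induces the confusion quantities
tp = 1 − F₂(c), fp = 1 − F₁(c) (and their unit-mass complements), which
trace the ROC as *c* sweeps the driver range.

Two exact consequences of the logistic choice are used throughout:

- **The logit-ROC is a straight line** with slope s₁/s₂ and intercept
  (μ₂ − μ₁)/s₂. The intercept is the *accuracy index*; the slope departs
  from 1 exactly when the variances are unequal. `logit_roc()` returns
  both the analytic line and an empirical regression cross-check.
- **The likelihood ratio** LR(x) = f₂(x)/f₁(x) is monotone when
  s₁ = s₂ and single-peaked otherwise. Criterion regions with LR < 1 are
  *lenient* (a yes there favors S1), regions with LR > 1 are *strict*.
  `unbiased_criterion()` solves LR = 1; `criterion_for_beta()` solves
  LR = β for the expected-value-optimal β returned by `optimal_beta()`,

\[ \beta^* = \frac{P(\text{S1})}{P(\text{S2})}\cdot
   \frac{B_{\text{correct reject}} + C_{\text{false alarm}}}
        {B_{\text{hit}} + C_{\text{miss}}} . \]

### AUC on a bounded driver range

Drivers are bounded (0–100 for handicap scores, roughly 0–120 dB HL), so
the observable ROC is a *segment*, not a full curve. `roc_auc()`
therefore defaults to the **partial** trapezoidal area under the realized
segment, which can legitimately fall below 0.5 even for informative
models — the rest of the curve is simply not observable on the range.
`mode = "closed"` appends the (0,0) and (1,1) corners and, on a wide
enough range, equals P(X₂ > X₁); the test suite verifies this against
Monte Carlo to 0.005.

### Driver orientation

The convention is that larger driver values favor S2. When the pooled
maximum-likelihood slope is negative, `orient_driver()` reflects the
driver (x ↦ offset − x, offset = observed maximum), the model is fit on
the reflected axis, and every derived criterion is mapped back by
`criterion_to_original()`. The reflection is an exact involution.

## Bayesian fitting and the slope gate

`fit_population()` fits (θ₁, θ₂) per population with vague independent
normal priors, θ₁ ~ N(0, 100²) and θ₂ ~ N(0, 10²) — wide relative to any
plausible decision curve on these driver scales, so the data dominate.
The default sampler is an adaptive random-walk Metropolis chain
(compiled; 20 000 draws after 5 000 burn-in) whose proposal is the
Cholesky factor of the inverse Hessian at the posterior mode, with
Robbins–Monro scale adaptation toward 30 % acceptance during burn-in
only (so the kernel used for inference is fixed). The chain uses R's
RNG: a `seed` argument gives bit-identical results without disturbing
the caller's RNG stream. A deterministic 201 × 201 grid integration
(`method = "grid"`) provides an independent cross-check of the
posterior summaries.

An SDT reading of a decision is only meaningful if the driver actually
drives the decision in both populations. `slope_test()` requires
P(θ₂ > 0) ≥ 1 − α (α = 0.01) per population; `build_sdt_model()` refuses
to assemble a model when either population fails, naming the failing
population. The pipeline then reports the verdict instead of curves
(`exploratory = TRUE` overrides the gate but flags the model).

## Imputation

Baseline and post scores are filled by a sequential single-imputation
chain (`impute_chain()`): THI baseline → GHSI baseline → THI post, each
step regressing the target on covariates screened in two ANOVA stages
(type-III partial F tests under sum-to-zero contrasts; stage 1 keeps
p < 0.15, stage 2 keeps p < 0.05). Predictions are conditional means,
clamped to the score range, with `imputed_*` flag columns recording
provenance.

This is *point* imputation: it preserves conditional means (the MCAR
calibration test shows RMSE ≈ σ and negligible bias) but understates
outcome-score variance and treats imputed values as known downstream.
Posterior intervals for cohorts with heavy missingness are therefore
somewhat optimistic; multiple imputation would be the extension point.

## Synthetic cohorts

`ground_truth()` + `simulate_cohort()` generate cohorts with known
generating parameters, for validation and power analysis. Defaults:

- n = 200 participants, P(S2) = 0.4 — a minority but substantial
  beneficial population, matching a cohort in which most decision-makers
  said yes yet under half saw an MCID-sized improvement.
- Device-evaluation decision driven by hearing loss on [5, 115] dB HL
  with θ_S1 = (−2.0, 0.05), θ_S2 = (−1.0, 0.05): equal scales
  (s = 20 dB), locations 40 vs 20 dB, i.e. a genuinely informative but
  strongly overlapping driver.
- Counseling decision driven by baseline THI on [0, 100] with
  θ_S1 = (−1.8, 0.03), θ_S2 = (−1.8, 0.06): unequal scales, producing a
  non-unit logit-ROC slope and a single-peaked likelihood ratio.
- MCAR missingness rates 0.03 / 0.37 / 0.44 for THI baseline, THI post,
  GHSI baseline — heavy, deliberately stressing the imputation chain.

Outcome scores are drawn by inverse-CDF sampling from truncated
distributions so that the MCID label reproduces the drawn membership
*exactly by construction*; there is no post-hoc clipping that could flip
labels. The generator emulates marginal driver distributions, decision
curves, and missingness; it does not attempt to reproduce any particular
cohort's empirical joint distribution of covariates.

## Numerical choices

- All likelihood-ratio work happens in log space via the exact logistic
  log-density; confusion quantities use `plogis` directly, so unit-mass
  conservation holds to ≤ 1e−12.
- Criterion equations LR(x) = β are solved by a 4 096-point sign-change
  scan plus `uniroot` refinement (tolerance 1e−12); residuals are at
  machine precision.
- The empirical logit-ROC regression excludes points with tp or fp
  within 1e−8 of 0 or 1, where the logit amplifies double-precision
  rounding; the analytic line is exact regardless.
- Typical validated problem sizes: cohorts of 150–10 000, fits at
  n = 250–4 000 per population, 100-replicate calibration studies. A
  full two-pair analysis of a 600-participant cohort runs in roughly a
  second on one CPU.

## Known limitations and design decisions

- **Marginal, not joint, decisions.** Two decisions recorded per
  participant are analyzed as two marginal datasets (collapsing the 2 × 2
  joint table over the other decision, `marginal_counts()`); the
  dependence between the two decisions is not modelled.
- **Device uptake after evaluation** (`decision_sedu`) is recorded and
  extractable but not analyzed by the default pipeline, because it is
  only defined for the subset that started an evaluation.
- **Single outcome dichotomy.** The MCID dichotomy discards the
  magnitude of improvement; the SDT model sees only S1/S2.
- **Recovery precision is information-limited.** With s = 20 on a
  110-unit driver range and n = 1000 per population, the flatter
  component's location and scale are intrinsically only identified to
  roughly 10–15 % relative error (a Fisher-information bound, confirmed
  by MLE-only simulation). Validation therefore asserts *mean* relative
  error across replicates and credible-interval coverage, not
  per-replicate success.
- **Point imputation** (above) understates uncertainty under heavy
  missingness.
- The lenient/strict vocabulary follows the standard convention
  (lenient ⇔ LR < 1) everywhere, including in reports.
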
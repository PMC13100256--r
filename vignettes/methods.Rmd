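---
title: "Association versus prediction for pulmonary artery compliance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association versus prediction for pulmonary artery compliance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacpredict)
```

## The scientific problem

Pulmonary artery compliance (PAC = stroke volume / pulmonary pulse
pressure, mL/mmHg) measures the pulsatile component of right ventricular
afterload, complementing pulmonary vascular resistance (PVR = transpulmonary
gradient / cardiac output, Wood units), which measures the steady-state
component. Low PAC is repeatedly found to be *associated* with mortality in
right-heart-catheterization (RHC) cohorts. Association, however, is not
prediction: a variable can carry a highly significant adjusted hazard ratio
and still add nothing to a clinician's ability to rank patients by risk,
because the information it carries is already present in routinely used
variables. PAC is the canonical suspect for this phenomenon: PAC and PVR
are tied by the resistance-compliance (RC) time, RC = PAC x PVR, an
approximately conserved time constant of the pulmonary circulation, so PAC
is close to a deterministic transform of variables a clinician already has.

`pacpredict` implements both halves of the argument as a reusable pipeline:

1. **Association stage** — adjusted Cox models for dichotomized PAC
   (cut at 3 mL/mmHg) within hemodynamic subgroups, and a 4-knot linear
   tail-restricted cubic spline hazard-ratio curve in continuous PAC
   anchored at the reference PAC of 3 mL/mmHg.
2. **Prediction stage** — Monte Carlo cross-validation (MCCV): repeatedly
   sample 2000 subjects, train a full Cox model on 1500 and score the
   held-out 500 by Harrell's concordance; refit "handicapped" models with
   one variable removed on the same partitions; compare the paired
   hold-out concordance distributions by ANOVA, paired contrasts, and a
   Bayesian region-of-practical-equivalence (ROPE) summary.

Because the motivating clinical database is not public, the package ships a
synthetic cohort generator that reproduces the *statistical structure* the
analysis depends on, so every stage is testable end to end.

## Hemodynamic derivations, QC and PH classification

From measured HR, sPAP, dPAP, mPAP, PAWP and CO the package derives

- PP = sPAP − dPAP (mmHg),
- TPG = mPAP − PAWP (mmHg),
- PVR = TPG / CO (Wood units),
- SV = 1000 · CO / HR (mL; the factor converts L/min to mL per beat),
- PAC = SV / PP (mL/mmHg).

SV in mL is required for PAC to land on the familiar mL/mmHg scale (a
typical referral population has median PAC near 2.4). When PP ≤ 0 — which
happens in real, artifact-prone tracings — PAC is flagged undefined rather
than propagated as a number; `dpap <= mpap <= spap` is never assumed or
silently repaired.

Quality control applies the standard non-physiologic ranges with *strict*
inequalities, exactly as printed in the QC literature: CO < 0.5 or > 15
L/min; mPAP < 5 or > 80; dPAP < 0 or > 70; sPAP < 7 or > 130; PAWP < 0 or
> 60 mmHg; HR < 10 or > 200 bpm; age under 18 or over 90 years. Boundary
values therefore pass. Exclusion audits count each row once, under the
first applicable reason in the documented order (age → date error → prior
transplant/VAD → hemodynamic ranges), matching how consort diagrams are
tallied sequentially.

PH classification follows the 2022 ESC/ERS hemodynamic rules: no PH when
mPAP ≤ 20 mmHg; pre-capillary (PAWP ≤ 15, PVR > 2), isolated post-capillary
(PAWP > 15, PVR ≤ 2) and combined pre- and post-capillary (PAWP > 15,
PVR > 2) otherwise; anything else with mPAP > 20 — e.g. PAWP ≤ 15 with
PVR ≤ 2 — is *undetermined*. The five labels partition the space of
complete (mPAP, PAWP, PVR) triples; records with an incomplete triple are
reported, not classified, and never silently dropped.

## The synthetic cohort generator

The generator emulates what the analysis needs and no more:

- **Marginals.** Age (truncated normal, median 64), gender (55% male),
  race (84/10/5/1% White/Black/Unknown/Other), BMI, HR, mPAP, PAWP and CO
  (lognormal with medians 28 kg/m², 75 bpm, 28 mmHg, 15 mmHg, 4.9 L/min),
  CCI (negative binomial, median 2), comorbidity prevalences (AF 26%,
  hypertension 68%, OSA 17%), BSA (truncated normal, mean 1.9 m²). Only
  medians and IQRs of the target population are known, so the families are
  documented approximations; every acceptance property the package tests
  is family-agnostic.
- **RC coupling.** An RC time τ is drawn lognormal (median 0.40 s, sdlog
  0.25 — the physiologic 0.3–0.7 s range) and PAC is set to
  τ / (0.06 · PVR), using the unit identity 1 WU = 0.06 mmHg·s/mL. This
  produces the inverse hyperbolic PAC–PVR relationship (and, through it, a
  strong negative rank correlation between PAC and mPAP) that makes PAC
  largely redundant given mPAP and PVR. The 0.40 s median was chosen once
  so the derived PAC median lands near the 2.4 mL/mmHg target; it is a
  calibration, not ground truth.
- **Pressure reconstruction.** sPAP and dPAP are reconstructed around
  mPAP from the implied pulse pressure PP = SV/PAC using the classical
  mPAP ≈ dPAP + PP/3 relation (`pp_split = 2/3`, configurable). Rows
  violating TPG > 0, dPAP > 0 or any QC range are rejected and redrawn,
  with the rejection count reported; a configuration rejecting more than
  99% of draws errors out.
- **Survival.** Event times follow a Weibull proportional-hazards model by
  inverse-transform sampling: T = scale · (−log U / exp(lp))^(1/shape).
  The linear predictor is assembled from user-specified terms (identity,
  log, or below-threshold indicator transforms), each centred at its
  cohort mean. Censoring is the minimum of an administrative horizon and
  a uniform dropout draw, independent of the event process. Defaults
  (shape 1.1, scale 22 y, horizon 15 y, dropout on (0, 30) y) were
  calibrated once to give roughly 35–40% observed deaths — the event
  fraction typical of large RHC referral cohorts. The true linear
  predictor and intended PAC are stored as ground-truth columns; deriving
  PAC back from the generated pressures reproduces the intended PAC to
  floating-point accuracy.

**What the generator does not emulate:** covariance among demographics and
comorbidities (they are sampled independently), waveform artifacts,
non-proportional hazards, competing risks, or the exact event counts and
hazard ratios of any real cohort. Passing tests therefore demonstrate that
the *methods* behave correctly under a known truth with the right coupling
structure, not that any particular clinical estimate is reproduced.

### The redundancy scenario

`make_redundancy_scenario()` builds the cohort on which the package's
headline comparison rests: the hazard depends only on age (log-HR 0.035/y)
and mPAP (0.030/mmHg) — clinically realistic effects giving hold-out
concordance near 0.65 — while PAC is RC-coupled to mPAP and PVR but carries
*zero conditional effect* by construction. Because only two variables carry
signal, removing either costs a clearly detectable few hundredths of
concordance (larger than in a real cohort, where many correlated predictors
share the signal), while removing PAC costs nothing beyond noise. That
qualitative pattern — association without incremental predictive value —
is the target, not any particular concordance value.

## The survival kernel

The statistical kernel is implemented from scratch (with the inner loops in
C++, as survival software conventionally does):

- **Cox partial likelihood.** Damped Newton–Raphson with step-halving,
  Efron's tie correction by default (Breslow available). Columns are
  centred and scaled internally so convergence — largest absolute score
  component below 1e−8 — is unit-free; coefficients and covariance are
  mapped back to the raw scale. The iteration cap is 50; a step is
  accepted when it does not decrease the partial likelihood beyond
  floating-point noise (relative slack 1e−9). Constant and exactly
  collinear columns are rejected by name; non-convergence is reported
  explicitly, never silently. Fits are validated in the test suite against
  brute-force partial-likelihood grid maximization (an independent oracle)
  and cross-checked against the `survival` package.
- **Harrell's concordance.** A pair is comparable when the earlier
  observed time is an event; event-versus-censored pairs tied on time are
  comparable with the event taken as failing first; event–event pairs tied
  on time are not comparable. Score ties count one half. These tie rules
  are frozen in tests against a literal O(n²) pair-enumeration oracle.
  Orientation: higher score = higher risk.
- **Restricted cubic spline.** The Harrell truncated-power form with 4
  knots (1 linear + 2 nonlinear columns), nonlinear columns scaled by the
  squared boundary-knot span; linear beyond the boundary knots by
  construction. Knots default to the 0.05/0.35/0.65/0.95 quantiles of the
  exposure — the conventional placement for 4 knots — and are overridable.
  The hazard-ratio curve is the exponentiated spline contrast against the
  reference (PAC 3 mL/mmHg by default), so adjustment covariates cancel
  exactly, the curve is exactly 1 at the reference, and the pointwise 95%
  band (delta method on the contrast) has zero width there.
- **Proportional-hazards diagnostic.** Scaled Schoenfeld residuals
  regressed on a time transform (Kaplan–Meier scaling by default), with
  per-covariate and global chi-square tests using the averaged-information
  approximation. It is calibrated under the null and powered against
  crossing hazards in the test suite.

## Association-stage decisions

- **Dichotomization boundary.** "Low PAC" is PAC strictly below the
  threshold; the boundary value 3.0 falls in the high group. The
  orientation of the reported hazard ratio is configurable and labelled
  (`low_vs_high` by default); flipping it inverts the HR exactly.
- **Adjustment set.** Age, gender, race, body-size term, CCI, atrial
  fibrillation, OSA, hypertension. Published descriptions of this analysis
  family are inconsistent about BMI versus BSA as the body-size term; the
  package defaults to BMI and accepts BSA (`body_size = "bsa"`).
- **Reference covariates.** For curve construction the reference level of
  each adjustment covariate is the mode (categorical/binary) or median
  (continuous); because the model has no interactions, these cancel in the
  hazard-ratio contrast and affect nothing — documented for transparency.
- **Subgroups.** PAWP ≤ 15 vs > 15 mmHg and PVR ≤ 2.2 vs > 2.2 WU, refit
  per subgroup (covariate effects re-estimated within each stratum) rather
  than modelled with interaction terms — the simplest reading of
  subgroup-table analyses; a subgroup with fewer than 2 events in either
  PAC arm is declined with a message.
- **PH-only sensitivity.** Restriction to mPAP > 20 mmHg, i.e. exactly the
  complement of the NO_PH class.

## Prediction-stage decisions

- **Sampling scheme.** Within a repetition, 2000 subjects are drawn
  without replacement and split 1500/500; across repetitions, independent
  redraws from the full cohort (subjects may recur across repetitions).
  Handicapped models are *refit* without the variable — removal, not
  coefficient-zeroing. All variants share the partitions within a
  repetition, so contrasts are paired by construction. The master seed
  spawns per-repetition sub-seeds; runs are exactly reproducible.
- **Failed repetitions** (non-convergence, no comparable pairs in the test
  set) are recorded and excluded from summaries, never imputed.
- **Frequentist comparison.** Both the omnibus one-way ANOVA across
  variants and per-handicap paired t contrasts are reported and labelled
  distinctly. MCCV repetitions share subjects, so these nominal p-values
  are approximate — a documented caveat, which is also why the Bayesian
  ROPE summary is the preferred effect-size statement.
- **Bayesian ROPE.** The paired mean concordance difference is estimated
  under a Student-t likelihood (fixed ν = 5 for heavy tails), a normal
  prior on the mean (sd 0.1 — diffuse on the concordance scale) and a
  half-normal prior on the scale. The posterior is computed by
  deterministic quadrature on a 200 × 200 (mean, log-scale) grid rather
  than MCMC: it is exact to grid resolution, needs no convergence
  diagnostics, and is fully reproducible. Reported: posterior mean, 95%
  highest-density interval, and the mass inside the ROPE |Δ| < 0.01 (an
  effect size of 0.01 on the concordance scale being the conventional
  threshold of practical relevance here).
- **Subgroups.** PH classes (NO_PH, PRECAP, IPCPH, CPCPH) or PVR bins with
  boundaries assigned to the lower bin at 2 and 3 WU and the top bin open
  above 5 (≤2, 2–3, 3–5, >5). When a stratum is smaller than the sample
  size, the scheme shrinks proportionally: five-sixths of the stratum
  rounded down to a multiple of four, split 3:1 (a 120-row stratum gives
  100 sampled, 75/25); strata under 40 rows are skipped with a message.

## Numerical choices and degenerate inputs

- Cox convergence: score tolerance 1e−8 (standardized scale), 50
  iterations, 20 step-halvings; singular information matrices and
  degenerate designs error with the offending column names.
- Concordance with zero comparable pairs (e.g. everything censored) is an
  explicit error, not NaN.
- Wald 95% intervals on the log-hazard scale throughout; the identity
  exp(log HR ± 1.96 se) = (CI low, CI high) holds to 1e−10 by
  construction and is asserted in tests.
- The ROPE posterior handles a zero-variance difference vector (a
  constant shift) as a point mass at the observed mean.
- Problem sizes used by the shipped test suite and acceptance script —
  cohorts of 2500–20000, 100-repetition MCCV at 2000/1500/500, 50-seed
  sweeps for the headline pattern, 200-replicate recovery studies — were
  chosen as the smallest sizes at which the tested properties are stable,
  and are stated in the tests themselves.

## Known limitations

- No stratified Cox, time-varying covariates, frailty terms, competing
  risks, cause-specific mortality, or baseline-hazard estimation beyond
  what the PH diagnostic needs; concordance is the only predictive metric
  (no time-dependent AUC or calibration), by design.
- The generator's independence assumptions (demographics, comorbidities)
  mean it cannot be used to study confounding structures among those
  covariates; it is built to validate the machinery, not to mimic any
  institution's case mix.
- The PH diagnostic uses the averaged-information approximation to the
  scaled-Schoenfeld test; per-covariate statistics can differ by a few
  percent from implementations that track the full per-event information.
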
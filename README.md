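# pacpredict

Association is not prediction. `pacpredict` is an R package for
right-heart-catheterization (RHC) survival analysis that keeps the two
questions apart for pulmonary artery compliance (PAC = SV/PP, mL/mmHg),
the pulsatile component of right ventricular afterload:

1. **Is PAC associated with all-cause mortality?** Adjusted Cox models for
   PAC dichotomized at 3 mL/mmHg (overall and within PAWP/PVR subgroups),
   and a 4-knot linear tail-restricted cubic spline hazard-ratio curve in
   continuous PAC, anchored at HR = 1 for PAC = 3 mL/mmHg.
2. **Does PAC improve mortality prediction?** Monte Carlo cross-validation:
   sample 2000 subjects 100 times, fit a full Cox model (age, gender, race,
   body size, CCI, atrial fibrillation, OSA, hypertension, mPAP, PAC) on
   1500, score the held-out 500 by Harrell's concordance, and compare
   against "handicapped" models refit with one variable removed — paired by
   partition — using ANOVA, paired contrasts, and a Bayesian
   region-of-practical-equivalence (ROPE ± 0.01) summary.

The package is aimed at researchers evaluating derived hemodynamic indices:
PAC is tied to PVR by the RC time (RC = PAC × PVR, an approximately
conserved time constant), so PAC is nearly a transform of variables already
in every model — the textbook setting where a strong adjusted hazard ratio
coexists with zero incremental predictive value.

It also ships the supporting machinery:

- hemodynamic derivations (PP, TPG, PVR, SV, PAC) with strict
  physiologic-range QC and 2022 ESC/ERS PH classification
  (NO_PH / PRECAP / IPCPH / CPCPH / UNDETERMINED);
- a from-scratch survival kernel — Cox partial likelihood (Efron/Breslow
  ties, C++ inner loops), Harrell's C under censoring, restricted cubic
  splines, scaled-Schoenfeld PH diagnostic — oracle-tested against brute
  force and cross-checked against the `survival` package;
- a calibrated synthetic RHC cohort generator (Table-1-like marginals,
  lognormal RC time coupling PAC to PVR, Weibull proportional-hazards
  survival, independent censoring) so the entire pipeline is testable
  without any clinical data.

## Worked example

The redundancy scenario is the package's headline construction: hazard
driven only by age and mPAP, PAC coupled to mPAP through the RC time but
carrying **zero conditional effect**.

```r
library(pacpredict)

co <- make_redundancy_scenario(n = 6000, seed = 42)

# association: low PAC (< 3 mL/mmHg) looks strongly prognostic
dichotomized_hr(co, threshold = 3)
#>   subgroup_label orientation       hr   ci_low  ci_high      p_value    n n_events
#> 1           none low_vs_high 1.350534 1.240134 1.470762 4.971656e-12 6000     2333

# prediction: removing PAC costs nothing; removing age or mPAP costs
mc <- run_mccv(co, mccv_config(seed = 42))   # 2000 sampled, 1500/500, 100 reps
compare_models(mc)
#> Omnibus ANOVA across variants: p = 3.224e-80 (approximate; reps share subjects)
#>       model mean_difference pairwise_p rope_mass post_mean    hdi_low  hdi_high n_pairs
#>   minus_age       0.0592800  1.976e-57 1.426e-52 5.858e-02  0.0554400 0.0617300     100
#>  minus_mpap       0.0297100  1.183e-45 6.772e-35 3.011e-02  0.0280500 0.0321000     100
#>   minus_pac       0.0002389  2.371e-01 1.000e+00 7.111e-05 -0.0002636 0.0003394     100
```

Reading the output: PAC is "significantly associated with mortality"
(adjusted HR 1.35 for low PAC, p ≈ 5e−12) — yet refitting the predictive
model without PAC changes mean hold-out concordance by 0.0002 with the
entire posterior inside the ±0.01 ROPE (`rope_mass = 1.0`), while removing
age or mPAP, the variables that actually drive the hazard, drops
concordance by 0.059 and 0.030 with p < 1e−40. Association without
incremental predictive value, on data where that is true by construction.

Other entry points: `generate_cohort()` / `generator_config()` (synthetic
cohorts), `annotate_cohort()` / `apply_exclusions()` (derivations, QC,
consort-style audit), `spline_hr_curve()` / `ph_only_sensitivity()`
(association stage), `subgroup_mccv()` (PH-type and PVR-bin subgroups),
`run_pipeline()` plus `inst/cli/pacpredict.R` (config-driven runs), and
`fit_cox()` / `harrell_c()` / `rcs_basis()` / `ph_diagnostic()` (the
kernel). The methods vignette (`vignettes/methods.Rmd`) documents the
models, defaults and design decisions.

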
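# mmpop

Population (nonlinear mixed-effects) analysis of glucose effectiveness
with the Bergman minimal model.

## What this package is for

After an intravenous glucose tolerance test (IVGTT) — a 0.3 g/kg glucose
bolus with serial glucose and insulin sampling, optionally
insulin-modified (IM-IVGTT) by a small insulin infusion at 20 min —
glucose disappearance reflects two mechanisms: the action of insulin, and
the ability of glucose to promote its own disposal (*glucose
effectiveness*). `mmpop` quantifies both across a heterogeneous cohort by
embedding the minimal model in a hierarchical statistical model and
estimating it by exact maximum likelihood (Monte-Carlo EM). It is aimed at
researchers pooling IVGTT studies who want population-level estimates,
covariate effects (diabetes status, BMI, body weight, test type) and
per-subject empirical-Bayes estimates, rather than subject-by-subject
fits.

The observation model for subject *i* is

```
dG/dt = -(GEZI + X(t)) G(t) + (GEZI + Xb) Gb,   G(0) = Gb + Dose/V
dX/dt = -p2 X(t) + p2 SI I(t),                  X(0) = SI Ib
y_ij ~ Normal(G(t_ij), (sigma * G(t_ij))^2)
```

with `I(t)` the measured insulin (linearly interpolated forcing),
`GEZI` glucose effectiveness at zero insulin (min⁻¹), `SI` insulin
sensitivity (min⁻¹ per pmol/L), `p2` the remote insulin-action rate
(min⁻¹) and `V` the glucose distribution volume (L). The population stage
is log-normal, `log theta_i ~ N(mu + D_i gamma, Sigma)`, with declarative
covariate effects (power models centered at study medians for continuous
covariates, proportional shifts for categorical ones).

Main entry points:

| function | purpose |
|---|---|
| `simulate_glucose()` | forward model under measured-insulin forcing |
| `em_fit()` | Monte-Carlo EM population fit |
| `total_minus2LL()`, `lrt()` | marginal likelihood and model comparison |
| `ebe_screen()`, `forward_select()` | covariate screening and forward selection |
| `disposal_integrals()`, `basal_noninsulin_fraction()` | insulin-dependent vs non-insulin-dependent disposal |
| `cohort_spec()`, `simulate_trial()` | synthetic IVGTT / IM-IVGTT trial generator |
| `run_pipeline()` | file-based pipeline (also via `inst/cli/popmm.R`) |

`pop_base_model()` and `pop_final_model()` encode the published
covariate-free and final covariate population models, e.g.
`GEZI = 0.0210 (1 - 0.473 T2D)` min⁻¹ and
`SI = 6.26e-5 (1 - 0.479 T2D)(1 - 0.345 IM)(BMI/25.3)^-2.14`.

## Worked example

Simulate a 40-subject virtual trial from the published final covariate
model, fit the covariate-free hierarchy, and look at the population
estimates:

```r
library(mmpop)

spec  <- cohort_spec(n_subjects = 40, true_pop = pop_final_model(), seed = 42)
trial <- simulate_trial(spec)
ds    <- filter_dataset(trial$subjects)   # drop samples before 5 min

fit <- em_fit(ds, settings = fit_settings(n_importance_samples = 100,
                                          max_iterations = 25, seed = 7))
print(fit)
#> <mm_fit> 40 subjects, 642 obs, 25 EM iterations (not converged)
#>   -2 log likelihood: 1554.5 (MC se 1.28)
#> <population_params>
#>   typical values: GEZI=0.02129, SI=2.421e-05, p2=0.03659, V=12.78
#>   IIV CV%: GEZI=48.9, SI=126, p2=34.4, V=38.8
#>   proportional error: 0.06941
```

The estimates are population typical values for this mixed cohort (~31%
T2D): glucose effectiveness ~0.021 min⁻¹, an insulin sensitivity pulled
well below the ND reference 6.26e-5 by the T2D/IM-IVGTT/BMI mix, a ~13 L
distribution volume, and the ~7% proportional residual error the data
were generated with — all within the sampling noise a 40-subject cohort
allows. The "not converged" tag means the strict smoothed-trace criterion
was not met within 25 iterations; `fit$trace` shows the estimates plateau
while Monte-Carlo wobble stays above the threshold.

Partition a subject's net glucose disposal at their true parameters:

```r
s1 <- trial$subjects[[1]]
th <- unlist(trial$truth[1, c("GEZI", "SI", "p2", "V")])
disposal_integrals(mm_params(th[1], th[2], th[3], th[4]), s1)
#>   subject_id   GD_NID    GD_ID fraction_NID T_end
#> 1      S0001 48.78778 1.395323    0.9721954   180
```

This subject drew a very low insulin sensitivity, so ~97% of their
integrated disposal over the 180-min test is non-insulin-dependent;
`cohort_fraction_summary()` and `rank_sum_test()` aggregate and compare
whole cohorts, where ND subjects keep a systematically larger
non-insulin-dependent share than T2D subjects.

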
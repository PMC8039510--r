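---
title: "Population analysis of glucose effectiveness with the minimal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population analysis of glucose effectiveness with the minimal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpop)
```

## The model

`mmpop` estimates glucose effectiveness and insulin sensitivity from
intravenous glucose tolerance tests (IVGTT), pooled across many subjects, by
fitting the Bergman minimal model inside a nonlinear mixed-effects
hierarchy.

Stage 1 describes one subject's glucose excursion after a bolus
(`Dose`, mmol, at t = 0), with time in minutes:

$$
\frac{dG}{dt} = -(GEZI + X(t))\,G(t) + (GEZI + X_b)\,G_b,
\qquad G(0) = G_b + Dose/V,
$$
$$
\frac{dX}{dt} = -p_2\,X(t) + p_2\,S_I\,I(t),
\qquad X(0) = S_I\,I_b,
$$

where \(I(t)\) is the *measured* insulin concentration, linearly
interpolated between samples and held constant beyond the measured range
(insulin is a forcing function, not a modeled state), and
\(X_b = S_I I_b\). The four parameters are `GEZI` (glucose effectiveness
at zero insulin, 1/min), `SI` (insulin sensitivity, 1/min per pmol/L),
`p2` (remote-action rate constant, 1/min) and `V` (glucose distribution
volume, L). Residuals are Gaussian with standard deviation proportional to
the prediction, \(y_{ij} \sim N(f_{ij}, (\sigma f_{ij})^2)\). We read the
reported proportional-error figure (0.0706) as this ~7% CV; the literal
reading "variance proportional to the prediction" gives a different unit
for sigma and is not what a dimensionless 0.0706 suggests.

Glucose samples before 5 minutes are excluded before fitting
(`filter_early_samples()`): the one-compartment model does not represent
the initial mixing phase. The t = 0 sample, when present, is excluded by
the same rule; the initial condition always uses the model-derived
\(G_b + Dose/V\), never a measurement. The bolus is 0.3 g/kg, converted
to mmol with a glucose molar mass of 180.16 g/mol.

Stage 2 places a log-normal population distribution over the individual
parameter vectors: \(\log\theta_i \sim N(\mu + D_i\gamma, \Sigma)\), with a
full (correlated) 4x4 covariance — the analysis reports a strong positive
GEZI-p2 correlation, so a diagonal Sigma would be misspecified. Covariate
effects enter the subject-level mean in two declarative forms
(`covariate_effect()`):

* `power_centered` — \(TV \cdot (x/x_{ref})^{\beta}\) for continuous
  covariates, centered at the study median (BMI 25.3 kg/m2, weight 75 kg
  by default, configurable);
* `proportional_shift` — \(TV \cdot (1 + \phi\, \mathbb{1})\) for 0/1
  covariates, which keeps the published coefficient \(\phi\) directly
  interpretable. Internally the shift is carried as
  \(\log(1+\phi)\), making the stage-2 mean linear in all coefficients.

`pop_base_model()` and `pop_final_model()` construct the published
covariate-free and final covariate parameter sets, including the final
formulas `GEZI = 0.0210 (1 - 0.473 T2D)`,
`SI = 6.26e-5 (1 - 0.479 T2D)(1 - 0.345 IM)(BMI/25.3)^-2.14` and
`V = 12.0 (weight/75)^0.865`. Two conventions reported alongside:
IIV CV% is \(100\sqrt{\Sigma_{ii}}\) (the printed IIV formula is garbled in
the source; this reading reproduces the quoted 0.021 x 0.461 = 0.0097
spread), and the +/- spread of a parameter is TV x CV/100
(`approx_param_sd()`), which reproduces the quoted T2D GEZI spread 0.0051
rather than the 0.0055 printed once — the source is internally
inconsistent between those two figures and we follow the one consistent
with its own IIV.

## Estimation: Monte-Carlo EM

Exact maximum-likelihood estimation of \((\mu, \gamma, \Sigma, \sigma)\)
uses an EM algorithm in which the individual log-parameters are the missing
data.

**E-step.** For each subject the conditional posterior
\(p(\log\theta_i \mid y_i)\) is summarized by importance sampling: the mode
is found with box-constrained quasi-Newton search (L-BFGS-B), the Hessian
at the mode is taken by central differences, and samples are drawn from a
*defensive mixture* proposal — half from a multivariate-t (df = 4)
centered at the mode with the Laplace curvature, half from the prior
\(N(m_i, \Sigma)\) itself — combined with balance-heuristic multiple
importance sampling; a third component recentered at the estimated
moments is added when the effective sample size falls below half the
draws. The prior component is not a nicety: when a parameter is weakly
identified for a subject (small insulin excursion leaves `SI` almost
unconstrained), its conditional posterior collapses onto the prior and is
strongly left-skewed on the log scale, and a symmetric mode-centered
proposal under-covers that tail, biasing the conditional mean upward by
several percent — which flat likelihood ridges then amplify into
population-level bias. Self-normalized weights give the conditional mean
and covariance, the expected relative residual sum of squares, and the
marginal likelihood of the subject. Effective sample sizes are tracked
and degenerate weights are warned about. All draws are seeded per (seed,
subject, iteration): fits are bit-reproducible and invariant to subject
order.

The mode search and the proposal are restricted to a fixed, generous
log-parameter box (GEZI 1e-5..0.5, SI 1e-9..1e-2, p2 1e-4..2 per min,
V 1..100 L). The box is far outside any physiological estimate; its role
is numerical, keeping line searches and proposal tails out of regimes
where the ODE becomes needlessly stiff. Draws outside the box get zero
weight.

**M-step.** All updates are closed-form: the fixed effects and covariate
coefficients by generalized least squares on the conditional means (the
stage-2 model is linear-Gaussian in \((\mu, \gamma)\)); \(\Sigma\) from
pooled conditional second moments, symmetrized and eigenvalue-floored to
stay SPD; \(\sigma^2\) from the pooled expected relative residual sum of
squares.

**Convergence** is declared when every estimate changes by less than
`convergence_rtol` (default 2e-3) for five consecutive iterations, on
traces smoothed over three iterations — raw per-iteration estimates carry
Monte-Carlo noise, so unsmoothed criteria either never trigger or trigger
spuriously. The -2 log-likelihood trace is non-increasing up to that
noise. Initial values come from quick per-subject MAP fits under a weak
prior (`init_population()`), with the glucose peak extrapolation supplying
a starting volume.

**Likelihood evaluation and model comparison.** `total_minus2LL()`
re-estimates each subject's marginal likelihood by fresh importance
sampling with *model-independent* per-subject seeds, so two nested models
evaluated on the same data share common random numbers and their
difference — the LRT statistic — has far smaller Monte-Carlo error than
either total. The Monte-Carlo standard error is reported alongside and is
used as slack when validating the sign of a likelihood-ratio difference.

**Standard errors.** Scores of the marginal likelihood are assembled from
E-step moments through the Fisher identity (the score of the marginal
likelihood equals the conditional expectation of the complete-data score);
the information matrix is estimated by the outer product of per-subject
scores, which avoids the second-derivative term of the full Louis
decomposition. A nonparametric subject bootstrap
(`standard_errors(method = "bootstrap")`) is available when the
outer-product estimate is suspect; a singular information matrix produces
a warning and a pseudo-inverse, not a silent answer.

## Covariate selection

`ebe_screen()` ranks candidate covariate-parameter associations on the
empirical conditional means of a covariate-free fit (Spearman correlation
for continuous covariates, rank-sum / Kruskal-Wallis for categorical).
Screening is advisory. `forward_select()` then adds candidates one at a
time — SI candidates first, then V, then GEZI, then p2, the order in which
prior evidence supports covariate dependence. The gate at each step is a
*profile* likelihood-ratio statistic: conditional-posterior importance
samples are cached once under the current model, and because the candidate
coefficient enters the marginal likelihood only through the stage-2 prior
density, the profile -2 log likelihood over the coefficient is an analytic
reweighting of those samples. Whatever Monte-Carlo or convergence error
the current model's estimates carry is common to every coefficient value
and cancels exactly in the ratio — the property that keeps the gate's
type-I error at its nominal level, where comparing two separately refit,
partially converged models does not (their independent Monte-Carlo wander
enters the difference directly). The candidate's design column is centered
so the coefficient direction is orthogonal to the population mean, making
the fixed-nuisance profile first-order equivalent to the full
likelihood-ratio test. Candidates passing the gate at p < 0.05 are refit
in full to estimate their coefficients. The stated precision criterion is quantified
as RSE < 50% (the source states the criterion without a threshold);
passing `rse_threshold = Inf` gates on the LRT alone, which is also the
configuration under which the selection procedure's type-I error can be
compared with the nominal 5% level. No backward-elimination pass is
performed, matching the described forward-only procedure.

## Disposal partitioning

With subject-level estimates in hand, net glucose disposal over a test is
split into a non-insulin-dependent and an insulin-dependent integral,

$$
GD_{NID} = \int_0^T GEZI \cdot G(t)\,dt, \qquad
GD_{ID} = \int_0^T X(t)\,G(t)\,dt,
$$

evaluated on the model-predicted continuous trajectories at the subject's
conditional-mean parameters (not on interpolated observations), by
trapezoid rule on a 0.1-min grid up to the subject's last measurement; a
refinement test guards the quadrature error. The basal-state analogue is
\(GEZI/(GEZI + S_I I_b)\) with the measured basal insulin. Dynamic
fractions are computed for IVGTT subjects by default (the insulin-modified
protocol's exogenous infusion makes the dynamic partition a different
quantity); an override flag includes IM-IVGTT subjects. Group summaries
are arithmetic mean +/- SD in percent, and the ND-vs-T2D comparison uses a
two-sided Wilcoxon rank-sum test — exact enumeration when both groups have
at most 10 subjects, tie-corrected normal approximation otherwise.

## The synthetic cohort generator

The raw clinical data behind the published analysis are not deposited, so
`mmpop` ships a virtual-trial generator (`cohort_spec()`,
`simulate_trial()`) that reproduces the *study conditions* rather than any
particular dataset:

* **Composition and covariates.** 497 subjects by default, 154/497 T2D,
  229/497 insulin-modified tests, sex 239 F / 217 M / 41 unrecorded; age
  41.4 +/- 16.9 yr (9.7-86), height 169 +/- 10.1 cm (130-196), pooled BMI
  28.0 +/- 6.76 kg/m2 (15.9-53.9). Truncated-normal samplers are
  moment-matched so the *truncated* mean hits the target. BMI is drawn per
  cohort (ND 26.6, T2D 31.0, same spread) with the mixture matching the
  pooled mean — T2D cohorts are heavier in every constituent study — and
  weight is derived as BMI x height^2 so the anthropometry is internally
  consistent (one of the three must be derived; weight is the least often
  designed-on). Age and sex are drawn independently of cohort, a
  simplification: the real T2D groups are also older.
* **Missing-covariate imputation** (`impute_missing()`) reproduces the
  pooled-study rules: group means for missing continuous values, sex drawn
  from reported proportions, algebraic completion when two of
  weight/height/BMI are present (height = 100 sqrt(weight/BMI) — the
  printed form "H = weight/BMI" is dimensionally impossible), and a
  documented synthetic surrogate for the anthropomorphic generator used in
  the original workflow: height from sex-specific normals (F 162 +/- 7,
  M 176 +/- 7 cm) and weight back-calculated from BMI.
* **Insulin forcing** profiles are synthetic — no measured profiles are
  available — and parameterized so users can substitute real ones: basal
  plus a fast first phase and a slower second phase, each
  `A (1 - e^(-t/rise)) e^(-t/decay)`. ND: basal 45 pmol/L, first phase
  ~500 (decay 12 min), second phase 120 (decay 45 min). T2D: marked
  fasting hyperinsulinemia at 220 pmol/L, a blunted first phase (150) and
  a large sustained second phase (500, decay 45 min) — calibrated toward
  the insulin exposure implied by the reported T2D disposal partition,
  which a milder profile cannot reproduce. Second-phase amplitudes are
  structurally capped so every profile returns to within a few percent of
  basal by the final knot, preserving the terminal-slope information that
  identifies GEZI. One tension is documented rather than hidden: the
  reported basal-state disposal fractions imply modest T2D basal insulin
  while the dynamic fractions imply much larger exposure; the generator
  matches the dynamic characteristic, so its basal-state fractions run
  lower than the reported ~89%. IM-IVGTT adds an
  exogenous response at 20 min of 2000 pmol/L per 0.04 U/kg (dose drawn
  0.03-0.05 U/kg, decay 10 min): a ~3 U intravenous insulin dose in ~4 L
  plasma transiently reaches a few thousand pmol/L, and this enriched
  signal is what makes remote-action kinetics well identified in
  insulin-modified tests. All amplitudes carry log-normal between-subject
  variability.
* **Schedules.** IVGTT: 180-360 min, 12-30 samples; IM-IVGTT: 180-240 min,
  12-22 samples; dense before 30 min, sparse later, always including t = 0
  and the endpoint.
* **Observations.** True parameters are drawn from the hierarchy
  (`sample_individual()`), the noiseless solution is perturbed as
  `y = f (1 + sigma eps)` and floored at 0.1 mmol/L (large noise draws
  must not produce non-physical values). Basal glucose (ND 5.1, T2D
  8.5 mmol/L) and insulin are stored as *measured* values: truth times an
  assay-level noise (2% glucose, 5% insulin) — the dynamic 7% proportional
  error also absorbs model misspecification, but a basal sample is a
  direct assay. True parameters are held in a separate table that is never
  written into the files the fitting pipeline reads.

What passing recovery tests on these cohorts does show: the estimation
machinery recovers the generating population values under the study's
design (sampling schedules, noise level, parameter variability, cohort
mix). What it does not show: robustness to features the generator lacks —
real insulin assay error and profile shapes, glucose kinetics beyond one
compartment in the first minutes, covariate correlations (age-cohort,
site effects), or data entry artifacts.

## Numerical choices

* The ODE system is solved with an adaptive Dormand-Prince 4(5) scheme
  (default rtol 1e-8/atol 1e-10 standalone; 1e-6/1e-8 inside EM loops,
  where likelihood differences, not absolute trajectories, matter).
  Forcing knots and output times are mandatory step boundaries, so the
  integrator never steps across a kink in I(t). Correctness is checked
  against the constant-insulin closed form
  \(G_b + (Dose/V) e^{-(GEZI + S_I I_b)t}\) and against an independent
  fixed-step RK4 integrator at 0.001 min.
* Importance-sampling defaults: 100 draws per subject per iteration
  (3x for likelihood reporting, 2x for scores), multivariate-t df 4.
* Sigma updates are eigenvalue-floored at 1e-8; degenerate (near-zero
  variance) hierarchies remain usable, which the shrink-to-zero recovery
  test exercises.
* Ties in the rank-sum test use midranks; the exact mode enumerates group
  assignments, so it remains valid under ties.
* The GEZI-monotonicity sanity property (larger GEZI, faster
  disappearance) holds while G is above basal; once G undershoots basal
  the return term reverses the sensitivity, so the property is asserted in
  the no-undershoot regime.

## Problem sizes used in the shipped experiments

The parameter-recovery experiment fits three replicate cohorts of 150
subjects simulated from the published covariate-free population values,
with 400 importance samples and up to 40 EM iterations each, and assesses
the median recovered values over the replicates: a single 150-subject
cohort's realized parameter means deviate from the nominal values with
standard errors of roughly 4% (GEZI) to 9% (SI) by pure sampling, so
single-cohort comparisons conflate cohort luck with estimator quality. The selection-calibration experiment uses 100
replicates of 60 subjects with one null candidate and reduced Monte-Carlo
settings; because the profile gate cancels the base model's estimation
error exactly, the reduced settings do not distort the test's level. These sizes
are the package's validation choices: large enough to test the claims,
small enough to run routinely.

## Known limitations

* Exact ML by Monte-Carlo EM converges slowly along nearly flat likelihood
  directions (here: GEZI vs basal insulin action vs p2 when insulin stays
  elevated through a test); the convergence criterion on smoothed traces
  stops the iteration, but genuinely flat directions are reported honestly
  through large RSEs rather than resolved.
* Insulin is a measured forcing; assay error in insulin propagates
  unmodeled into the glucose likelihood.
* The generator's insulin profiles and basal distributions are plausible
  parameterizations, not reproductions of the unavailable study profiles;
  quantities that depend on the integrated insulin exposure (e.g. the
  printed disposal-fraction percentages 72.8%/48.8%) are reproduced in
  *direction* but not gated in value.
* One-compartment glucose kinetics; the first five minutes are excluded
  rather than modeled.
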
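---
title: "Methods: flip-flop depot pharmacokinetics in depotpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flip-flop depot pharmacokinetics in depotpk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depotpk)
```

## The model and its assumptions

`depotpk` analyses plasma concentration–time data from long-acting
intramuscular depots with a one-compartment disposition model driven by
first-order release from the depot. Writing $k_e = (CL/F)/(V/F)$, the
closed-form (Bateman) solution is

$$C(t) = \frac{D \, K_A}{(V/F)\,(K_A - k_e)}
  \left(e^{-k_e t} - e^{-K_A t}\right),$$

with the analytic limit $C(t) = (D/V)\,k\,t\,e^{-kt}$ when $K_A \to k_e$.
The assumptions are: linear (dose-proportional) disposition, a single
well-mixed central compartment, first-order release of the entire depot
amount, and no lag between injection and the start of release. Simultaneous
injections at two sites are modelled as one depot holding the summed dose —
per-site release is not identifiable from plasma concentrations. Without
intravenous reference data absolute bioavailability $F$ is not identifiable
either, so clearance and volume are apparent quantities ($CL/F$, $V/F$) and
$F$ is deliberately not a model parameter.

The defining feature of these depot formulations is **flip-flop kinetics**:
$K_A < k_e$, so the terminal slope of the plasma profile measures release
from the depot, not elimination. `is_flip_flop()` tests the condition and
`terminal_half_life()` returns $\ln 2 / \min(K_A, k_e)$.

**Units.** Time is in hours, concentration in ng/mL, dose in mg/kg
(total across sites), $CL/F$ in L/h/kg and $V/F$ in L/kg. One mg/kg over
one L/kg is 1000 ng/mL; that single conversion constant is defined once in
the model layer.

**Identifiability.** The Bateman form is invariant under exchanging $K_A$
and $k_e$ when the volume is rescaled to preserve $K_A/V$ (the test suite
asserts this symmetry). Concentration data alone therefore cannot say which
rate is release and which is elimination; the package resolves the ambiguity
by always reporting the flip-flop branch ($K_A < k_e$), which is the
physically motivated reading for slow-release depots, and warns when the two
branches sit within 0.1% of each other.

## Noncompartmental analysis

`nca_single()` reports per-animal Cmax, Tmax (earliest time attaining the
maximum, the conventional tie rule), Cmin (minimum quantifiable value),
linear-trapezoid AUC(0–last quantifiable) and the concentration at a
requested nominal time (day 14 = 336 h by default). Choices that the data
format forces:

- **AUC method.** The linear trapezoid is the default because it is the
  minimal defensible rule for sparse schedules; linear-up/log-down is
  available (`auc_method = "linuplogdown"`) for profiles with long
  mono-exponential tails.
- **BLQ handling.** A below-limit record at $t=0$ is a pre-dose sample and
  is entered as 0. Embedded and trailing BLQ records are excluded rather
  than imputed, avoiding the bias choices that LOD/2 substitution imports;
  `blq_rule = "half_lloq"` provides that substitution when comparability
  with LOD/2-based analyses matters.
- **Censoring is applied at analysis time**: any value below the working
  LLOQ argument is treated as BLQ regardless of the incoming flag, so
  re-analysis at a stricter limit needs no data editing.
- **`c_at` is the observed record** at the nominal time, never an
  interpolation: the quantity summarised in study tables is a measured
  sample.

Group summaries (`nca_summarize()`) are per-animal NCA first, then mean and
$n-1$ SD per group; single-animal groups report the value with an absent SD.
NCA is never run on pooled mean profiles, which would discard the per-animal
scatter the SD columns exist to report.

## Naive-pooled fitting

`fit_naive_pooled()` concatenates all animals of one species × formulation
arm into a single dataset and minimises
$\sum_i w_i (y_i - C(t_i; \theta))^2$ by Levenberg–Marquardt
(`minpack.lm::nls.lm`) over $\log \theta$, which enforces positivity by
construction. Serial-sacrifice designs pool naturally: each animal simply
contributes its single record.

- **Weighting** defaults to uniform — plain least squares on untransformed
  concentrations, matching a vanilla `lsqnonlin`-style regression; $1/\hat y$
  and $1/\hat y^2$ schemes (weights recomputed from the current prediction)
  are available when the dynamic range warrants them.
- **BLQ records are excluded** from the objective by default. A censored
  likelihood (M3-type) is a different estimator, not a default to slip in
  silently; LOD/2 inclusion is available behind `blq = "half_lloq"`.
- **Initialization** is multi-start: an NCA-informed start (terminal slope
  of the pooled means for the slow rate, dose over trapezoidal AUC for
  $CL/F$, the observed Tmax inverted through the peak-time relation for
  $k_e$) plus 10 log-uniform draws from the box $CL/F \in [10^{-3}, 10^2]$,
  $V/F \in [10^{-2}, 10^3]$, $K_A \in [10^{-5}, 10]$, seeded so fits are
  deterministic. The best objective wins.
- **Convergence** uses relative function and step tolerances of $10^{-10}$
  with at most 2000 evaluations per start; failure across all starts returns
  a diagnostic result with `converged = FALSE` rather than an error.
- **Branch selection**: if the optimum lands on the conventional branch it
  is swapped to the flip-flop branch using the exact exchange symmetry
  ($CL/F$ unchanged, $K_A^{new} = k_e^{old}$, $V^{new} = CL/K_A^{old}$),
  which leaves the residual sum of squares bit-identical.

**%RSE.** Parameter precision is reported as $100 \cdot SE/\hat\theta$ from
the linearized covariance $s^2 (J^T W J)^{-1}$ at the optimum, with $J$
taken with respect to $\log\theta$ — the standard error of $\log\theta$ *is*
the relative standard error of $\theta$, so no delta-method step is needed.
A rank-deficient Jacobian yields flagged infinite RSEs with the fit
retained. The straight-line test harness checks the covariance code against
`summary.lm`'s closed form to $10^{-8}$.

## Viral-load statistics

`mww_exact()` implements the one-sided two-sample Mann–Whitney–Wilcoxon
test with mid-ranks for ties. The p-value is **exact by complete
enumeration**: conditional on the pooled values, all
$\binom{n_1+n_2}{n_1}$ group-label assignments are enumerated and the
p-value is the fraction with a U statistic at least as extreme as observed.
This is tie-correct by construction — no continuity or tie adjustments are
approximated. Enumeration runs whenever the arrangement count is at most
$10^6$ (the 8-vs-8 efficacy design gives 12,870); beyond the cap a
tie-corrected normal approximation with continuity correction takes over
and is flagged in the result.

Undetectable viral loads enter the ranks **at the detection limit**
(700 copies/mL), tying all undetectable animals. Any value that preserves
their rank below every detectable animal gives identical p-values (the
`censor_policy` options 0 and limit/2 exist to make that explicit), so the
choice carries no inferential weight while avoiding imputation.
`pairwise_panel()` runs the three pairwise tests per
challenge-day × tissue × sampling-day stratum, Bonferroni-adjusts with
factor 3 (`min(1, 3p)`), and defaults to the protective one-sided direction
(treated below untreated). Strata missing a group are skipped with a
warning rather than failing the panel.

## The synthetic-data generator

`simulate_pk_study()` emulates the three preclinical designs: rats and
rabbits at 40 mg/kg total with eleven- and thirteen-point schedules out to
672 h, mice at 140 mg/kg under a serial-sacrifice design (a fresh animal per
time point, hence no within-animal correlation), all with a 2 ng/mL LLOQ
and three animals per arm. Per-animal parameters are lognormal around the
truth (mean-preserving, CV `iiv_cv`), residual error is proportional plus
additive, negative draws are truncated to zero, and anything below the LLOQ
is emitted as a censored record. `simulate_efficacy_study()` emulates the
prevention design: two challenge-day strata × three groups × eight mice,
per-group detection probabilities, detectable loads lognormal truncated
above the 700 copies/mL limit.

**Calibration, not measurement.** The error defaults — 20% proportional CV,
0.5 ng/mL additive SD, 25% inter-animal CV — are calibration choices made
once so that simulated group scatter (e.g. Cmax CV) lands in the 20–45%
range that small-n intramuscular depot studies report; no published
residual-error model exists for these data. The generator reproduces the
designs' structure, not everything about real data: it has no injection-site
granuloma dynamics, no time-varying release, no assay batch effects and no
within-animal correlation beyond shared parameters. Passing tests therefore
demonstrate estimator correctness under the stated error model, not
robustness to model misspecification.

A noise-free rat simulation from the published SSPN-9 truth stays
quantifiable at 504 h (the closed form gives 2.55 ng/mL, just above the
2 ng/mL limit) and censors at 672 h; the observed studies lost
quantifiability by day 21, a reminder that the fitted curve and sparse noisy
observations need not cross the LLOQ on the same day.

## Numerical and reporting choices

- Equal-rate branch: $|K_A - k_e|/k_e < 10^{-8}$ switches to the limit
  form; the test suite verifies continuity across the switch at $10^{-4}$.
- Tiny negative concentrations from floating-point cancellation are clamped
  to zero.
- Report rounding is **half away from zero** (`round_half_up()`):
  half-lives to integer hours, fold ratios to one decimal. Recomputing the
  published half-lives from the rounded two-significant-figure $K_A$
  estimates reproduces the printed values exactly for five of the eight
  arms and within 1 h for the rest (the published table clearly derived
  half-lives from unrounded estimates), so checks allow ±1 h there.
- Fold-extension ratios are computed, never transcribed: 109 h over the
  5.6 h oral mouse half-life gives 19.5, while 89 h over the 4.79 h oral
  rat half-life gives 18.6 at one-decimal rounding (18.58 unrounded) — a
  reported 18.5 for that pair is a rounding discrepancy the package does
  not reproduce. The oral references live in
  `inst/extdata/oral_reference_half_lives.yaml` with notes; rabbits have no
  published oral reference, so no rabbit ratio is reported.

## Problem sizes

The test suite and acceptance script size their simulations for tight
feedback: 200 random parameter sets for the closed-form-vs-ODE oracle, 100
seeded replicates (3 rats, 20% proportional CV, 25% IIV) for the recovery
study with 5 random starts per fit, full enumeration up to 8 per group for
the rank test, and 400 null replicates for p-value validity. The whole
suite runs in well under a minute on one core; the recovery study is the
dominant cost and scales linearly in replicates.

## Known limitations

- Naive pooling is the estimator by design; it understates uncertainty
  relative to mixed-effects modelling and cannot separate inter-animal from
  residual variability.
- %RSE comes from local linearization; for weakly identified parameters
  (apparent volume under flip-flop, where the profile constrains $V$ only
  through the coefficient) it can be optimistic. The published volume RSEs
  of 30–55% are consistent with what the recovery simulations show.
- No lag time, parallel depots or multi-compartment disposition: the model
  statement is first-order release into one compartment, and adding
  structure the sparse schedules cannot identify would only destabilise the
  fits.
- AUC extrapolation to infinity from observed data ($\lambda_z$-based) is
  out of scope — the model-implied $D/(CL/F)$ is provided instead and is
  clearly labelled as a model quantity.
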
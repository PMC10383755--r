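# depotpk

Pharmacokinetic analysis of long-acting injectable (LAI) depot formulations
that exhibit **flip-flop kinetics** — the regime in which drug release from an
intramuscular depot is slower than systemic elimination, so the terminal
plasma slope reflects depot release rather than the drug's intrinsic
disposition. The package was built around multi-species preclinical studies
of semi-solid prodrug nanoparticle (SSPN) depots of the antiretroviral
emtricitabine (FTC), but the machinery applies to any depot formulation whose
plasma profile follows first-order release into a one-compartment system.

It is aimed at pharmacokineticists and formulation scientists who need a
tested, reproducible path from tidy concentration–time tables to
noncompartmental summaries, naive-pooled model fits, half-life-extension
ratios and viral-load efficacy statistics.

## The model

Plasma concentration after an intramuscular dose `D` (mg/kg) follows the
Bateman solution of the one-compartment disposition model with first-order
absorption input from the depot:

```
C(t) = D·KA / [ (V/F)·(KA − ke) ] · ( e^(−ke·t) − e^(−KA·t) ),   ke = (CL/F)/(V/F)
```

with apparent clearance `CL/F` (L/h/kg), apparent volume `V/F` (L/kg) and
depot-release rate constant `KA` (1/h); a dedicated analytic branch handles
`KA ≈ ke`. Flip-flop kinetics holds when `KA < ke`, and the terminal
half-life is `ln 2 / min(KA, ke)`. The form is symmetric under exchanging
`KA` and `ke` (with the volume rescaled), so the fitting layer always reports
the flip-flop branch.

Around the model the package provides:

- `nca_single()` / `nca_table()` / `nca_summarize()` — per-animal
  noncompartmental analysis (Cmax, Tmax, Cmin, linear-trapezoid AUC(0–last),
  concentration at a nominal time) with LLOQ censoring;
- `fit_naive_pooled()` — naive-pooled nonlinear least squares in
  log-parameter space with multi-start initialization and linearized %RSE;
- `mww_exact()` / `pairwise_panel()` — exact one-sided
  Mann–Whitney–Wilcoxon tests (full enumeration, mid-ranks for ties) with
  Bonferroni correction, for viral-load comparisons under a detection limit;
- `simulate_pk_study()` / `simulate_efficacy_study()` — seeded synthetic
  study generators reproducing the rat/rabbit/mouse depot designs;
- `run_pipeline()` — simulate (or read CSV) → NCA → fit → statistics →
  report, plus a thin CLI at `inst/cli/depotpk.R`.

## Worked example

Simulate a three-rat study (40 mg/kg total, the 1.5 h–28 day schedule,
2 ng/mL LLOQ) from a flip-flop truth, then analyse it:

```r
library(depotpk)

truth  <- pk_params(cl_f = 2.44, v_f = 5.02, ka = 0.0078)  # ke ≈ 0.49 >> KA
design <- rat_design()
sim <- simulate_pk_study(truth, design,
                         error_model(prop_cv = 0.2, add_sd = 0.5,
                                     iiv_cv = 0.25, seed = 42),
                         formulation = "SSPN-9")

nca_summarize(nca_table(sim, lloq = 2, c_at_time = 336))
#>   species formulation n cmax_mean  cmax_sd tmax_mean tmax_sd ...
#> 1     rat      SSPN-9 3  124.0461 41.08119        18 10.3923 ...

fit <- fit_naive_pooled(pooled_dataset(sim, design$dose), seed = 42)
fit
#> Naive-pooled depot-model fit
#>             estimate       %RSE
#>   CL/F         2.764       16.8
#>   V/F          4.804       38.7
#>   KA        0.009172       21.8
#>   n_obs 29, RSS 1.546e+04, converged TRUE
#>   flip-flop TRUE; terminal half-life 75.6 h

half_life_extension(round_half_up(fit$terminal_half_life), 4.79)
#> [1] 15.9
```

The group Cmax (124 ± 41 ng/mL) and AUC scatter come from the generator's
25% inter-animal and 20% proportional error; the fit recovers the truth
within its reported precision (`KA` 0.0092 vs 0.0078 at 22% RSE), flags the
flip-flop regime, and converts the terminal half-life into a fold extension
over the 4.79 h oral reference half-life in rats. With zero noise the fit
returns the truth to machine precision and the half-life prints as 89 h.

Published naive-pooled estimates for the eight studied
species × formulation arms ship as `sspn_reference_parameters()`, and
`oral_reference_half_lives()` reads the oral reference half-lives from
`inst/extdata/oral_reference_half_lives.yaml`.

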
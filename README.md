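# vancopk

Population pharmacokinetics and model-informed precision dosing of
intravenous vancomycin in patients with chronic kidney disease (CKD).

Vancomycin is cleared renally and has a narrow therapeutic window: troughs
below ~10 mg/L risk treatment failure and resistance, troughs above ~20 mg/L
risk nephrotoxicity. In CKD the usual nomograms perform poorly, so dosing is
best driven by a population pharmacokinetic model plus Bayesian feedback
from measured troughs. `vancopk` implements that workflow end to end for a
one-compartment model derived in a CKD cohort (creatinine clearance
< 60 ml/min), and ships a synthetic-cohort generator so every component can
be exercised and validated without any patient data.

## The model

One-compartment kinetics with constant-rate IV infusions:

- Clearance: `CL_i = [θ_CL + θ_CrCl · (CrCl_i − 33.8)] · exp(η_CL,i)` (L/h),
  with CrCl the Cockcroft–Gault estimate on total body weight (ml/min) and
  33.8 ml/min the derivation-cohort mean,
- Volume: `V_i = θ_V · TBW_i · exp(η_V,i)` (L),
- `η ~ N(0, ω²)` (log-normal inter-individual variability),
- Residual error: `C_obs = C_pred · (1 + ε_p) + ε_a`, with
  `ε_p ~ N(0, σ²_prop)` and `ε_a ~ N(0, σ²_add)`.

Default parameters (the final published estimates): θ_CL = 1.30 L/h,
θ_CrCl = 0.023 L/h per ml/min, θ_V = 1.23 L/kg, ω_CL = 0.544, ω_V = 0.225,
σ_add = 2.46 mg/L, σ²_prop = 0.001.

Within an interval the infusion solution is
`C(t) = (R₀/CL)(1 − e^{−k t'})` during the infusion and exponential decay
afterwards (`k = CL/V`), superposed over the dose history; steady-state
troughs use the closed form
`C_ss,min = (R₀/CL)(1 − e^{−k·T_inf}) e^{−k(τ−T_inf)} / (1 − e^{−kτ})`.

What the package provides:

- **Simulation** — subject and cohort simulation, visual predictive checks
  (`simulate_subject`, `simulate_cohort`, `vpc`).
- **Synthetic cohorts** — truncated-normal CKD demographics, protocol
  dosing (15–20 mg/kg q12/24 h, 2 g per-infusion cap, 500 mg/h rate cap) and
  sparse pre-dose trough sampling (`cohort_spec`, `generate_cohort`).
- **Estimation** — Laplace/FOCE-I approximate marginal-likelihood population
  fitting with a compiled inner loop, MAP-Bayesian individual estimation,
  subject-resampling bootstrap, stepwise covariate selection, and
  PRED/IPRED/IWRES/CWRES diagnostics (`fit_population`, `map_estimate`,
  `bootstrap_fit`, `stepwise_covariate_selection`, `compute_cwres`).
- **Dosing** — enumeration and ranking of loading + maintenance regimens
  that attain a trough target window under the clinical safety envelope
  (30 mg/kg loading / 20 mg/kg maintenance caps, 2 g per infusion,
  500 mg/h), both a priori and after measured troughs with hold advice
  (`recommend_initial`, `adjust_regimen`).
- **Validation** — MAE/MSE/RMSE/PE%/MAPE% accuracy metrics, Bland–Altman
  limits of agreement, and an external-validation driver
  (`accuracy_metrics`, `bland_altman`, `external_validate`).
- **I/O and CLI** — a NONMEM-style rectangular CSV dataset format, YAML/JSON
  model configuration, and a `vancopk` command-line tool
  (`inst/cli/vancopk`) with `cohort`, `simulate`, `fit`, `validate`,
  `dose-init` and `dose-adjust` subcommands.

## Worked example

Initial dosing for a 72-year-old, 57.8 kg man with serum creatinine
150 µmol/L (Cockcroft–Gault CrCl 32.2 ml/min), targeting troughs of
15–20 mg/L:

```r
library(vancopk)
cov <- patient_covariates(age = 72, sex = "male", tbw = 57.8, scr = 150)
recommend_initial(cov, target_window(15, 20))
#> 3 feasible regimen(s); top 3:
#>   loading_dose maintenance_dose interval predicted_ss_trough
#> 1         1250             1000       36               15.99
#> 2         1500             1000       36               15.99
#> 3            0             1000       36               15.99
#>   predicted_trough_at_first_measure time_to_window daily_dose score
#> 1                             9.486            144      666.7 1.507
#> ...
```

The engine proposes 1000 mg every 36 h with a 1250 mg load: the predicted
steady-state trough is 16.0 mg/L (1.5 mg/L from the window midpoint), and
the loading dose brings the pre-dose trough into the window by 144 h,
whereas without a load it would not enter the window within the 168 h
search horizon.

Suppose the measured trough at 71.5 h is 24.8 mg/L — far above the typical
prediction. MAP-Bayesian adjustment individualises the patient and
re-searches:

```r
doses <- expand_regimen(regimen(1000, 36, loading_dose = 1250), 72)
adjust_regimen(cov, doses, data.frame(time = 71.5, value = 24.8),
               target_window(15, 20))
#> MAP: CL 0.548 L/h, V 60.4 L (eta_cl -0.84); hold 78 h;
#> predicted now 23.1 mg/L
#> 2 feasible regimen(s); top 2:
#>   loading_dose maintenance_dose interval predicted_ss_trough ...
#> 1            0              250       24               17.11
```

The individual clearance estimate drops to 0.55 L/h (η_CL = −0.84), dosing
should be withheld for 78 h (the predicted concentration decays below
20 mg/L by then, on a 6 h nursing grid), and the maintenance regimen falls
to 250 mg q24h.

The same is available from a shell:

```sh
inst/cli/vancopk dose-init --age 72 --sex male --weight-kg 57.8 \
  --scr-umol 150 --target 15-20 --out recommendation.json
```

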
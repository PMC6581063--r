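---
title: "Methods: the vancomycin CKD population model, its estimator, and the dosing engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the vancomycin CKD population model, its estimator, and the dosing engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancopk)
```

## The structural and statistical model

`vancopk` implements a one-compartment model for intravenous vancomycin in
chronic kidney disease. All doses are constant-rate infusions (vancomycin
is never given as an IV push; zero-duration events are rejected). For a
dose with rate $R_0$ infused over $[t_s, t_e)$, the contribution at time
$t$ is

$$C(t) = \begin{cases}
0 & t < t_s\\
\frac{R_0}{CL}\left(1 - e^{-k (t - t_s)}\right) & t_s \le t \le t_e\\
\frac{R_0}{CL}\left(1 - e^{-k D}\right) e^{-k (t - t_e)} & t > t_e
\end{cases}$$

with $k = CL/V$ and $D = t_e - t_s$; the full profile is the superposition
over the dose history. Time zero is the start of the first infusion and all
times are in hours.

Subject-level parameters:

$$CL_i = \max\!\big(\theta_{CL} + \theta_{CrCl}\,(CrCl_i - 33.8),\ 0.1\big)
  \, e^{\eta_{CL,i}}, \qquad
  V_i = \theta_V \cdot TBW_i \cdot e^{\eta_{V,i}}$$

* **Renal function.** $CrCl$ is the Cockcroft–Gault estimate computed on
  total body weight, in ml/min, with serum creatinine converted from
  µmol/L at 88.42 µmol/L per mg/dL. We deliberately do not normalise to
  body surface area: Cockcroft–Gault is not a BSA-normalised quantity, and
  the model was built for the raw clinical estimate. (Published summary
  tables sometimes label such values "ml/min/1.73 m²"; we treat that as a
  labelling convention and use raw CG throughout.)
* **Covariate form.** Only the typical value 1.30 L/h and the slope
  0.023 L/h per ml/min are reported for the clearance model, not the
  functional form. We adopt a *centred linear* model,
  $\theta_{CL} + \theta_{CrCl}(CrCl - 33.8)$, with 33.8 ml/min the
  derivation-cohort mean CrCl, so that the printed typical clearance is
  literally the model value for the average derivation patient. An
  uncentred variant is available by setting `crcl_ref = 0` in
  `population_parameters()`. This is a declared convention of this
  package, since reported estimates alone do not identify the functional
  form.
* **Clearance floor.** The typical clearance is floored at 0.1 L/h so the
  elimination rate constant stays positive for extreme low CrCl; the floor
  is essentially never active inside the population the model was derived
  for (CrCl roughly 10–60 ml/min).
* **Variability.** $\eta$'s are independent normal on the log scale
  (exponential random effects), $\omega_{CL} = 0.544$ and
  $\omega_V = 0.225$ by default. Reported IIV percentages are interpreted
  as $\omega \times 100$ — the most common reporting convention; the
  alternative $\sqrt{e^{\omega^2}-1}$ CV convention would give almost the
  same numbers at these magnitudes (e.g. 0.544 → 58.9%).
* **Residual error.** Combined proportional-then-additive:
  $y = f\,(1+\varepsilon_p) + \varepsilon_a$ with
  $\mathrm{Var}(\varepsilon_p) = \sigma^2_{prop} = 0.001$ (≈ 3.2% CV) and
  $\mathrm{SD}(\varepsilon_a) = \sigma_{add} = 2.46$ mg/L. Simulated
  concentrations are truncated at zero (a concentration cannot be
  negative); truncation counts are reported via an attribute. The order of
  the proportional and additive components is immaterial for the
  distribution; we fix the parameterisation above.

## The synthetic-cohort generator

`cohort_spec()` encodes the study conditions the rest of the package is
validated under: 80 subjects (derivation) or 112 (validation), truncated
normal age 71.7 ± 13.0 y on [31, 97], weight 57.8 ± 15.7 kg on
[33.6, 103.8], serum creatinine 150.6 ± 73.6 µmol/L (151.1 ± 83.1 for
validation), 63.7% male, and rejection sampling to CG CrCl < 60 ml/min
(the CKD inclusion criterion; on by default). Dosing follows the in-house
protocol: a per-subject weight-based dose drawn uniformly from 15–20 mg/kg,
rounded to 250 mg, capped at 2 g per infusion, infused at at most
500 mg/h (minimum 1 h), every 12 h when CrCl ≥ 40 ml/min and every 24 h
otherwise. Sampling is sparse troughs: a per-subject count drawn as a
rounded normal (2.1 ± 1.3 clipped to 1–4 for the derivation profile;
2.3 ± 1.3 clipped to 1–5 for validation) placed 0–1 h before scheduled
doses inside the 120 h horizon.

Choices the source material does not pin down, fixed here once:

* covariates are sampled independently (no joint covariance is published);
  an optional age–creatinine correlation knob exists but defaults to 0;
* serum creatinine is truncated below at 40 µmol/L to avoid absurd CrCl;
* the "0–1 h before a scheduled dose" trough placement is our convention —
  sampling-time records are not published;
* prescriber adherence to the protocol is assumed exact.

What the generator therefore does *not* emulate: covariate correlations,
time-varying renal function, dose-holding and protocol deviations,
non-trough (peak) samples, assay censoring at a lower limit of
quantification, and record errors. Passing tests on these cohorts show the
estimator and dosing logic are correct *under the stated model*; they do
not certify performance on hospital data with those extra features.

## Population estimation

`fit_population()` maximises a Laplace-type approximation of the marginal
likelihood. For subject $i$ with residual variance
$g^2_{ij} = \sigma^2_{add} + \sigma^2_{prop} f_{ij}^2$ evaluated at the
*individual* prediction (the "with interaction" choice), the penalised
objective

$$h_i(\eta) = \tfrac12 \sum_j\left[\log(2\pi g^2_{ij}) +
  \frac{(y_{ij}-f_{ij}(\eta))^2}{g^2_{ij}}\right] +
  \tfrac12\,\eta^\top\Omega^{-1}\eta + \tfrac12\log\det(2\pi\Omega)$$

is minimised over $\eta$ by a damped Newton iteration with an analytic
gradient (the infusion model's $\partial f/\partial\eta$ has a closed
form). The first 8 iterations use the Gauss–Newton Hessian; if
convergence has not been reached by then — which happens for very sparse
subjects where Gauss–Newton zig-zags — the iteration switches to the exact
Hessian obtained by central differences of the analytic gradient.
Convergence is declared at gradient $\le 10^{-7}$. Each subject
contributes

$$-2\log L_i \approx 2 h_i(\hat\eta) - p\log 2\pi + \log\det H_i$$

where $H_i$ is the Gauss–Newton Hessian at the mode for
`method = "foce_i"` (the default, matching first-order conditional
estimation with interaction) or the exact numerical Hessian for
`method = "laplace"`. Subjects with no observations contribute zero, and a
variance component set (or estimated) to zero pins the corresponding
$\eta$ at zero, so the degenerate model reduces exactly to weighted
nonlinear least squares — a reduction the test suite checks against an
independent least-squares fit.

The outer problem optimises
$(\theta_{CL}, \theta_{CrCl}, \theta_V, \omega_{CL}, \omega_V,
\sigma_{add}, \sigma^2_{prop})$ — plus one slope per selected extra
covariate — with `nlminb`, log-transforming every positive-constrained
parameter, warm-starting the per-subject modes across outer iterations,
and using three optimisation starts by default (the first at the supplied
initial values, the rest jittered with SD 0.2 on the transformed scale) as
a guard against local optima. The per-subject likelihood loop is compiled
(Rcpp); a pure-R reference path (`engine = "r"`) implements the identical
algorithm and the two are cross-checked in the tests, as are the
standalone MAP modes against the modes the fitter stores.

Standard errors come from the numerical Hessian of the objective on the
transformed scale (covariance $2H^{-1}$ for a $-2\log L$ objective),
delta-method mapped to relative standard errors; for log-scale parameters
the RSE is reported as $100 \times SE(\log)$. Eta-shrinkage is
$1 - SD(\hat\eta)/\omega$ with the $n-1$ SD. `compute_cwres()` implements
the conditional weighted residuals by first-order linearisation about the
posterior-mode etas ($E = IPRED - A\hat\eta$,
$\mathrm{Cov} = A\Omega A^\top + \mathrm{diag}(g^2)$, CWRES
$= \mathrm{Cov}^{-1/2}(y - E)$), alongside PRED, IPRED and IWRES.

We do not attempt bit-compatibility with NONMEM: the validation standard is
parameter recovery on simulated data, not objective-function matching.
Bootstrap (`bootstrap_fit`) resamples subjects with replacement, refits
each replicate from the original estimates with a single start, reports
percentile intervals, and flags the result unstable above 20% replicate
failures. Stepwise covariate selection uses forward inclusion at
ΔOFV > 3.84 and backward retention at ΔOFV ≥ 6.63 by default
(χ²(1) at p = 0.05 and 0.01 — the original thresholds are not published);
the CrCl effect is carried by the built-in slope (fixed at 0 while
unselected) and other candidates enter as centred linear effects.

## The dosing engine

`recommend_initial()` enumerates maintenance doses on the 250 mg grid up
to min(20 mg/kg, 2 g), intervals {12, 24, 36, 48} h, and loading doses on
the grid 20–30 mg/kg (capped at 2 g, always including "no load"), predicts
with $\eta = 0$, and keeps regimens whose closed-form steady-state trough
lies inside the target window. Because candidates are generated inside the
constraint envelope, emitted recommendations cannot violate it — a
property the tests verify over randomised patients. The interval grid
extends the 12/24 h protocol with 36/48 h because stage 4–5 CKD routinely
needs longer intervals; configure `allowed_intervals = c(12, 24)` to
recover the strict protocol.

Ranking is deterministic: distance of the predicted steady-state trough
from the window midpoint, with ties broken by shorter time-to-window
(first pre-dose trough inside the window, simulated over a 168 h horizon),
then lower daily dose, then smaller loading dose. Clinical tools of this
kind typically present candidate dose pairs for human choice; the explicit
deterministic score is this package's own design, documented so its
ranking can be audited. Patients with CrCl ≥ 60 ml/min produce a warning, not
an error, mirroring the deployment rule that the tool is for CrCl < 60.

`adjust_regimen()` MAP-individualises from all measured troughs (no
last-value-carried-forward), re-runs the search with the individual
parameters, and, when the predicted concentration at decision time (the
last observation time by default) exceeds the window's upper bound, advises
a hold: the smallest multiple of 6 h (a nursing-round-compatible grid, our
choice) after which the predicted concentration has decayed to the upper
bound.

## Numerical choices and degenerate inputs

* Residual variances are floored at $10^{-12}$ inside the likelihood, so a
  zero-noise model remains evaluable.
* Infusion intervals are half-open $[t_s, t_e)$; overlapping infusion
  windows and unsorted dose lists are structural errors, not warnings.
* `steady_state_trough()` requires interval > infusion duration.
* Dose-linearity holds exactly at fixed infusion duration; note that the
  500 mg/h rate rule makes duration itself dose-dependent above 500 mg.
* Empty observation sets are valid for MAP estimation (prior mode) and
  invalid for population fitting (which needs ≥ 2 subjects with data).
* Percentile VPC bands use 8 equal-count time bins and the 5th/50th/95th
  percentiles by default; empty bins are reported as missing, never
  interpolated.

## Problem sizes used in the validation suite

The automated checks run at sizes chosen to make sampling noise small
relative to the tolerances while staying desk-scale: parameter recovery
and CWRES calibration on 200 simulated subjects (~3 troughs each,
560 observations); bootstrap coverage with 200 replicates on an
80-subject cohort; covariate-selection operating characteristics on
20 effect-present and 20 null replicates of 80 subjects (both phases at
ΔOFV 3.84, the criterion being characterised); dosing safety over 1000
randomised patients; the closed form against adaptive ODE integration on
100 randomised instances at $10^{-6}$ relative tolerance; and the accuracy
metrics against a loop-written reference at $10^{-12}$ on 1000 random
vectors.

## Known limitations

* One compartment only; two-compartment or nonlinear elimination models
  are out of scope, as are dialysis patients (excluded from the source
  population).
* AUC/MIC-based dose optimisation is deliberately not implemented; the
  targets are trough windows.
* Time-varying covariates (notably serum creatinine) are rejected by the
  dataset layer rather than modelled.
* The estimator is a conditional-mode approximation; like all such
  estimators it can be biased for variance components under very sparse
  designs — trough-only sampling particularly limits information about
  $\omega_V$, which is why its recovery tolerance is the widest.
* External-validation metrics default to population predictions
  ($\eta = 0$, a priori scoring); `use_ipred = TRUE` scores posterior
  individual predictions instead.
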
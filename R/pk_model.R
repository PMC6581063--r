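#' Patient covariates
#'
#' Bundle the demographic and laboratory covariates the model needs: age, sex,
#' total body weight and serum creatinine.  These are the four inputs from
#' which renal function (Cockcroft-Gault creatinine clearance) and the
#' weight-scaled volume of distribution are derived.
#'
#' @param age Age in years (> 0, < 140).
#' @param sex `"male"` or `"female"`.
#' @param tbw Total body weight in kg (> 0).
#' @param scr Serum creatinine in µmol/L (> 0).
#' @param height Height in m; optional, not used by the model.
#' @return An object of class `patient_covariates`.
#' @examples
#' patient_covariates(age = 72, sex = "male", tbw = 57.8, scr = 150)
#' @export
patient_covariates <- function(age, sex, tbw, scr, height = NA_real_) {
  check_number(age, "age", lower = 0, strict_lower = TRUE)
  check_number(tbw, "tbw", lower = 0, strict_lower = TRUE)
  check_number(scr, "scr", lower = 0, strict_lower = TRUE)
  check_number(height, "height", lower = 0, allow_na = TRUE)
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"))
  structure(
    list(age = as.numeric(age), sex = sex, tbw = as.numeric(tbw),
         scr = as.numeric(scr), height = as.numeric(height)),
    class = "patient_covariates"
  )
}

#' @export
print.patient_covariates <- function(x, ...) {
  cat(sprintf("Patient: %s, %g y, %g kg, SCr %g umol/L (CG CrCl %.1f ml/min)\n",
              x$sex, x$age, x$tbw, x$scr, cockcroft_gault(x)))
  invisible(x)
}

# µmol/L per mg/dL for creatinine (fixed conversion constant).
SCR_UMOL_PER_MGDL <- 88.42

#' Cockcroft-Gault creatinine clearance
#'
#' Creatinine clearance estimated from age, total body weight, sex and serum
#' creatinine using the Cockcroft-Gault equation on total body weight (the
#' form used in routine practice):
#' \deqn{CrCl = \frac{(140 - age) \times TBW}{72 \times SCr_{mg/dL}}
#'       \times (0.85\ \mathrm{if\ female})}
#' Serum creatinine in µmol/L is converted to mg/dL with the constant
#' 88.42 µmol/L per mg/dL.  No body-surface-area normalisation is applied.
#'
#' @param cov A [patient_covariates()] object.
#' @return Creatinine clearance in ml/min.
#' @examples
#' cockcroft_gault(patient_covariates(40, "male", 72, 88.42))  # 100 ml/min
#' @export
cockcroft_gault <- function(cov) {
  stopifnot(inherits(cov, "patient_covariates"))
  if (cov$age >= 140) {
    stop("age must be < 140 years for Cockcroft-Gault (got ", cov$age, ")",
         call. = FALSE)
  }
  if (cov$scr <= 0) {
    stop("scr must be > 0 (got ", cov$scr, ")", call. = FALSE)
  }
  cg_crcl(cov$age, cov$sex == "female", cov$tbw, cov$scr)
}

# vectorised CG core used by the cohort generator and dataset readers
cg_crcl <- function(age, female, tbw, scr) {
  scr_mgdl <- scr / SCR_UMOL_PER_MGDL
  (140 - age) * tbw / (72 * scr_mgdl) * ifelse(female, 0.85, 1)
}

#' Population pharmacokinetic parameters
#'
#' Container for the final population model: a one-compartment model with
#' clearance depending linearly on Cockcroft-Gault creatinine clearance
#' (centred at the derivation-cohort mean), volume of distribution scaled
#' linearly by total body weight, log-normal (exponential) inter-individual
#' variability on clearance and volume, and a combined additive +
#' proportional residual-error model.  Defaults are the final published
#' estimates for vancomycin in chronic kidney disease.
#'
#' @param tvcl Typical clearance at the reference CrCl, L/h.
#' @param theta_crcl Clearance slope per ml/min of CrCl, L/h per (ml/min).
#' @param crcl_ref Reference CrCl the clearance model is centred at, ml/min.
#'   Set to 0 for an uncentred linear model.
#' @param tvv Typical volume of distribution per kg body weight, L/kg.
#' @param omega_cl SD of the log-scale random effect on clearance.
#' @param omega_v SD of the log-scale random effect on volume.
#' @param sigma_add Additive residual SD, mg/L.
#' @param sigma_prop2 Proportional residual variance (dimensionless; the
#'   stored quantity is the variance of the proportional error term).
#' @param cl_floor Lower bound applied to typical clearance, L/h; keeps the
#'   elimination rate constant positive at extreme low CrCl.
#' @param extra_cl,extra_v Optional additional linear covariate effects,
#'   named lists of `list(slope=, ref=)` keyed by covariate name; used by the
#'   covariate-selection machinery.
#' @return An object of class `population_parameters`.
#' @examples
#' population_parameters()                       # published final model
#' population_parameters(theta_crcl = 0)         # no renal covariate
#' @export
population_parameters <- function(tvcl = 1.30, theta_crcl = 0.023,
                                  crcl_ref = 33.8, tvv = 1.23,
                                  omega_cl = 0.544, omega_v = 0.225,
                                  sigma_add = 2.46, sigma_prop2 = 0.001,
                                  cl_floor = 0.1,
                                  extra_cl = list(), extra_v = list()) {
  check_number(tvcl, "tvcl", lower = 0, strict_lower = TRUE)
  check_number(theta_crcl, "theta_crcl")
  check_number(crcl_ref, "crcl_ref", lower = 0)
  check_number(tvv, "tvv", lower = 0, strict_lower = TRUE)
  check_number(omega_cl, "omega_cl", lower = 0)
  check_number(omega_v, "omega_v", lower = 0)
  check_number(sigma_add, "sigma_add", lower = 0)
  check_number(sigma_prop2, "sigma_prop2", lower = 0)
  check_number(cl_floor, "cl_floor", lower = 0, strict_lower = TRUE)
  structure(
    list(tvcl = tvcl, theta_crcl = theta_crcl, crcl_ref = crcl_ref,
         tvv = tvv, omega_cl = omega_cl, omega_v = omega_v,
         sigma_add = sigma_add, sigma_prop2 = sigma_prop2,
         cl_floor = cl_floor, extra_cl = extra_cl, extra_v = extra_v),
    class = "population_parameters"
  )
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("Population PK parameters (one-compartment IV infusion)\n")
  cat(sprintf("  CL  = %.4g + %.4g x (CrCl - %.4g) L/h   [floor %.3g]\n",
              x$tvcl, x$theta_crcl, x$crcl_ref, x$cl_floor))
  cat(sprintf("  Vd  = %.4g L/kg x TBW\n", x$tvv))
  cat(sprintf("  IIV: omega_CL %.4g, omega_V %.4g (log scale SD)\n",
              x$omega_cl, x$omega_v))
  cat(sprintf("  Residual: additive SD %.4g mg/L, proportional var %.4g\n",
              x$sigma_add, x$sigma_prop2))
  for (nm in names(x$extra_cl)) {
    cat(sprintf("  + CL covariate %s: slope %.4g (ref %.4g)\n",
                nm, x$extra_cl[[nm]]$slope, x$extra_cl[[nm]]$ref))
  }
  for (nm in names(x$extra_v)) {
    cat(sprintf("  + V covariate %s: slope %.4g (ref %.4g)\n",
                nm, x$extra_v[[nm]]$slope, x$extra_v[[nm]]$ref))
  }
  invisible(x)
}

#' Typical (population) clearance at a given creatinine clearance
#'
#' Centred linear covariate model: `tvcl + theta_crcl * (crcl - crcl_ref)`,
#' floored at `pop$cl_floor` so the elimination rate constant stays positive.
#' At the reference CrCl the typical clearance equals `tvcl` exactly.
#'
#' @param crcl Creatinine clearance, ml/min (> 0).
#' @param pop A [population_parameters()] object.
#' @param extra Optional named numeric vector of additional covariate values
#'   matching `pop$extra_cl`.
#' @return Typical clearance in L/h.
#' @export
typical_clearance <- function(crcl, pop = population_parameters(),
                              extra = NULL) {
  check_number(crcl, "crcl", lower = 0, strict_lower = TRUE)
  cl <- pop$tvcl + pop$theta_crcl * (crcl - pop$crcl_ref)
  for (nm in names(pop$extra_cl)) {
    eff <- pop$extra_cl[[nm]]
    cl <- cl + eff$slope * (extra[[nm]] - eff$ref)
  }
  max(cl, pop$cl_floor)
}

# typical V (L) for a subject; linear per-kg model with optional covariates
typical_volume <- function(tbw, pop, extra = NULL) {
  v_perkg <- pop$tvv
  for (nm in names(pop$extra_v)) {
    eff <- pop$extra_v[[nm]]
    v_perkg <- v_perkg + eff$slope * (extra[[nm]] - eff$ref)
  }
  max(v_perkg, 1e-3) * tbw
}

#' Individual pharmacokinetic parameters
#'
#' Build subject-level clearance and volume from covariates and log-scale
#' random effects: `cl = CL_typ(CrCl) * exp(eta_cl)` and
#' `v = tvv * TBW * exp(eta_v)`.  The exponential construction keeps both
#' strictly positive for any finite eta.
#'
#' @param cov A [patient_covariates()] object.
#' @param eta_cl,eta_v Log-scale random effects (0 gives the typical subject).
#' @param pop A [population_parameters()] object.
#' @param extra Optional named numeric vector of extra covariate values.
#' @return An object of class `individual_parameters` with elements `cl`
#'   (L/h), `v` (L), `k` (1/h) and the etas.
#' @export
individual_parameters <- function(cov, eta_cl = 0, eta_v = 0,
                                  pop = population_parameters(),
                                  extra = NULL) {
  stopifnot(inherits(cov, "patient_covariates"))
  check_number(eta_cl, "eta_cl")
  check_number(eta_v, "eta_v")
  crcl <- cockcroft_gault(cov)
  cl <- typical_clearance(crcl, pop, extra) * exp(eta_cl)
  v <- typical_volume(cov$tbw, pop, extra) * exp(eta_v)
  structure(
    list(cl = cl, v = v, k = cl / v, eta_cl = eta_cl, eta_v = eta_v,
         crcl = crcl),
    class = "individual_parameters"
  )
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat(sprintf(
    "Individual PK: CL %.3g L/h, V %.3g L, k %.4g 1/h, t1/2 %.3g h (eta_CL %.3g, eta_V %.3g)\n",
    x$cl, x$v, x$k, log(2) / x$k, x$eta_cl, x$eta_v))
  invisible(x)
}

#' Infusion dose events
#'
#' Validate a table of constant-rate infusion events.  All vancomycin doses
#' are infusions (never IV push), so every event needs a strictly positive
#' duration; infusion windows must not overlap.
#'
#' @param time Start times in h since first dose (>= 0, non-decreasing).
#' @param amount Dose amounts in mg (> 0).
#' @param duration Infusion durations in h (> 0); default derives the
#'   duration from the 500 mg/h rate cap via [default_infusion_duration()].
#' @return A `data.frame` with columns `time`, `amount`, `duration`, `rate`.
#' @export
dose_events <- function(time, amount,
                        duration = default_infusion_duration(amount)) {
  if (length(time) == 0) {
    return(data.frame(time = numeric(), amount = numeric(),
                      duration = numeric(), rate = numeric()))
  }
  amount <- rep_len(amount, length(time))
  duration <- rep_len(duration, length(time))
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("dose times must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(amount)) || any(amount <= 0)) {
    stop("dose amounts must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop("infusion durations must be finite and > 0 (bolus dosing is not supported)",
         call. = FALSE)
  }
  o <- order(time)
  if (any(diff(time) < 0)) {
    stop("dose events must be sorted by time", call. = FALSE)
  }
  time <- time[o]; amount <- amount[o]; duration <- duration[o]
  ends <- time + duration
  if (length(time) > 1 && any(time[-1] < ends[-length(ends)] - 1e-9)) {
    stop("overlapping infusion windows in dose history", call. = FALSE)
  }
  data.frame(time = time, amount = amount, duration = duration,
             rate = amount / duration)
}

#' Default infusion duration under the rate cap
#'
#' Duration implied by the maximum administration rate (default 500 mg/h)
#' with a 1 h minimum infusion time for small doses.
#'
#' @param amount Dose in mg.
#' @param max_rate Maximum infusion rate, mg/h.
#' @param min_duration Minimum infusion duration, h.
#' @return Duration in h (vectorised over `amount`).
#' @export
default_infusion_duration <- function(amount, max_rate = 500,
                                      min_duration = 1) {
  pmax(amount / max_rate, min_duration)
}

#' Dosing regimen
#'
#' A loading + maintenance schedule: an optional loading infusion at time 0
#' followed by repeated maintenance infusions every `interval` hours.
#'
#' @param maintenance_dose Maintenance dose, mg (> 0).
#' @param interval Dosing interval, h (> 0).
#' @param loading_dose Loading dose, mg (0 means no load).
#' @param first_maintenance_offset Time from the start of the loading
#'   infusion to the first maintenance dose, h.  Defaults to `interval` when
#'   a loading dose is given and 0 otherwise.
#' @return An object of class `regimen`.
#' @export
regimen <- function(maintenance_dose, interval, loading_dose = 0,
                    first_maintenance_offset = if (loading_dose > 0) interval else 0) {
  check_number(maintenance_dose, "maintenance_dose", lower = 0,
               strict_lower = TRUE)
  check_number(interval, "interval", lower = 0, strict_lower = TRUE)
  check_number(loading_dose, "loading_dose", lower = 0)
  check_number(first_maintenance_offset, "first_maintenance_offset", lower = 0)
  structure(
    list(loading_dose = loading_dose, maintenance_dose = maintenance_dose,
         interval = interval,
         first_maintenance_offset = first_maintenance_offset),
    class = "regimen"
  )
}

#' @export
print.regimen <- function(x, ...) {
  if (x$loading_dose > 0) {
    cat(sprintf("Regimen: load %g mg, then %g mg q%gh (first maintenance at %g h)\n",
                x$loading_dose, x$maintenance_dose, x$interval,
                x$first_maintenance_offset))
  } else {
    cat(sprintf("Regimen: %g mg q%gh\n", x$maintenance_dose, x$interval))
  }
  invisible(x)
}

#' Expand a regimen into explicit dose events
#'
#' @param reg A [regimen()] object.
#' @param horizon Time horizon in h; doses starting at or before `horizon`
#'   are included.
#' @param max_rate,min_duration Infusion-duration rule, see
#'   [default_infusion_duration()].
#' @return A dose-event `data.frame` as from [dose_events()].
#' @export
expand_regimen <- function(reg, horizon, max_rate = 500, min_duration = 1) {
  stopifnot(inherits(reg, "regimen"))
  check_number(horizon, "horizon", lower = 0, strict_lower = TRUE)
  times <- numeric(); amounts <- numeric()
  if (reg$loading_dose > 0) {
    times <- 0; amounts <- reg$loading_dose
  }
  mt <- seq(reg$first_maintenance_offset, horizon, by = reg$interval)
  times <- c(times, mt)
  amounts <- c(amounts, rep(reg$maintenance_dose, length(mt)))
  dose_events(times, amounts,
              default_infusion_duration(amounts, max_rate, min_duration))
}

# Precompute the time-geometry of (sample times x dose events); only the
# rate constant k and clearance vary across parameter evaluations, so the
# fitting hot loop re-uses these matrices.
conc_geometry <- function(t, doses) {
  nt <- length(t); nd <- nrow(doses)
  if (nd == 0 || nt == 0) {
    return(list(nt = nt, nd = nd))
  }
  ts <- matrix(doses$time, nt, nd, byrow = TRUE)
  dur <- matrix(doses$duration, nt, nd, byrow = TRUE)
  tm <- matrix(t, nt, nd)
  active <- tm > ts
  m1 <- pmin(pmax(tm - ts, 0), dur)      # time infused into this dose
  m2 <- pmax(tm - (ts + dur), 0)         # time since end of this infusion
  list(nt = nt, nd = nd, rate = doses$rate, m1 = m1, m2 = m2,
       active = active)
}

# concentrations for precomputed geometry at given (cl, k)
conc_from_geometry <- function(geom, cl, k) {
  if (geom$nd == 0) return(numeric(geom$nt))
  contrib <- (1 - exp(-k * geom$m1)) * exp(-k * geom$m2) * geom$active
  as.numeric(contrib %*% geom$rate) / cl
}

# d(conc)/dk for the same geometry (used by analytic gradients)
dconc_dk_from_geometry <- function(geom, cl, k) {
  if (geom$nd == 0) return(numeric(geom$nt))
  e1 <- exp(-k * geom$m1); e2 <- exp(-k * geom$m2)
  term <- (geom$m1 * e1 - geom$m2 * (1 - e1)) * e2 * geom$active
  as.numeric(term %*% geom$rate) / cl
}

#' Predicted concentration under a dose history
#'
#' Closed-form one-compartment constant-rate-infusion solution with
#' superposition over doses.  For a dose with rate `R0` running from `ts` to
#' `te`, its contribution at time `t` is 0 before `ts`,
#' `(R0/CL) (1 - exp(-k (t - ts)))` during the infusion, and
#' `(R0/CL) (1 - exp(-k D)) exp(-k (t - te))` after it ends, with
#' `k = CL/V` and `D` the infusion duration.
#'
#' @param t Times in h since first dose (vectorised, >= 0).
#' @param doses A dose-event `data.frame` from [dose_events()] or
#'   [expand_regimen()].
#' @param ind An [individual_parameters()] object (or any list with `cl`, `v`).
#' @return Concentrations in mg/L, one per element of `t`.
#' @export
concentration <- function(t, doses, ind) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  doses <- dose_events(doses$time, doses$amount, doses$duration)
  geom <- conc_geometry(t, doses)
  conc_from_geometry(geom, ind$cl, ind$cl / ind$v)
}

#' Steady-state trough concentration
#'
#' Closed-form trough (pre-dose) concentration at steady state under
#' repeated identical infusions:
#' \deqn{C_{ss,min} = \frac{R_0}{CL} (1 - e^{-k T_{inf}})
#'       \frac{e^{-k(\tau - T_{inf})}}{1 - e^{-k\tau}}}
#' with `R0` the infusion rate, `Tinf` the infusion duration and `tau` the
#' dosing interval.
#'
#' @param reg A [regimen()] object (only the maintenance part matters at
#'   steady state).
#' @param ind An [individual_parameters()] object.
#' @param max_rate,min_duration Infusion-duration rule.
#' @return The steady-state trough in mg/L.
#' @export
steady_state_trough <- function(reg, ind, max_rate = 500, min_duration = 1) {
  stopifnot(inherits(reg, "regimen"))
  tinf <- default_infusion_duration(reg$maintenance_dose, max_rate,
                                    min_duration)
  tau <- reg$interval
  if (tau <= tinf) {
    stop("interval must exceed the infusion duration (interval ", tau,
         " h, duration ", tinf, " h)", call. = FALSE)
  }
  r0 <- reg$maintenance_dose / tinf
  k <- ind$cl / ind$v
  (r0 / ind$cl) * (1 - exp(-k * tinf)) * exp(-k * (tau - tinf)) /
    (1 - exp(-k * tau))
}
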
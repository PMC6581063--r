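#' Cohort specification for synthetic CKD patients
#'
#' Describes the marginal distributions of a synthetic chronic-kidney-disease
#' cohort: truncated-normal age, weight and serum creatinine, Bernoulli sex,
#' protocol dosing (15-20 mg/kg at 12 or 24 h intervals under the 2 g and
#' 500 mg/h caps) and sparse trough sampling.  Defaults reproduce the
#' derivation cohort: n = 80, age 71.7 +/- 13.0 y (range 31-97), weight
#' 57.8 +/- 15.7 kg (range 33.6-103.8), serum creatinine 150.6 +/- 73.6
#' µmol/L, 63.7% male, 2.1 +/- 1.3 troughs per subject (clipped to 1-4)
#' over the first 120 h of therapy.
#'
#' @param n_subjects Number of subjects.
#' @param age_mean,age_sd,age_range Age distribution, years.
#' @param tbw_mean,tbw_sd,tbw_range Total-body-weight distribution, kg.
#' @param scr_mean,scr_sd,scr_min Serum-creatinine distribution, µmol/L;
#'   truncated below at `scr_min` to avoid absurd creatinine clearances.
#' @param male_fraction Probability of male sex.
#' @param samples_mean,samples_sd,samples_range Troughs per subject
#'   (rounded normal, clipped to `samples_range`).
#' @param horizon Simulation horizon, h.
#' @param ckd_only If `TRUE` (default), subjects whose Cockcroft-Gault CrCl
#'   is >= 60 ml/min are rejected and resampled, mirroring the CKD
#'   inclusion criterion.
#' @param dose_per_kg_range Protocol weight-based dose range, mg/kg.
#' @param interval_crcl_cutoff CrCl (ml/min) at or above which dosing is
#'   q12h; below it q24h.
#' @param dose_rounding,max_dose,max_rate Dose rounding grid (mg), per-
#'   infusion cap (mg) and rate cap (mg/h).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 80,
                        age_mean = 71.7, age_sd = 13.0,
                        age_range = c(31, 97),
                        tbw_mean = 57.8, tbw_sd = 15.7,
                        tbw_range = c(33.6, 103.8),
                        scr_mean = 150.6, scr_sd = 73.6, scr_min = 40,
                        male_fraction = 0.637,
                        samples_mean = 2.1, samples_sd = 1.3,
                        samples_range = c(1, 4),
                        horizon = 120, ckd_only = TRUE,
                        dose_per_kg_range = c(15, 20),
                        interval_crcl_cutoff = 40,
                        dose_rounding = 250, max_dose = 2000,
                        max_rate = 500) {
  stopifnot(n_subjects >= 1,
            age_range[1] < age_range[2], tbw_range[1] < tbw_range[2],
            male_fraction >= 0, male_fraction <= 1,
            samples_range[1] >= 1, samples_range[1] <= samples_range[2],
            horizon > 0)
  if (age_sd <= 0 || tbw_sd <= 0 || scr_sd <= 0) {
    stop("covariate SDs must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Validation-cohort specification
#'
#' [cohort_spec()] with the temporal validation cohort's defaults:
#' n = 112, age 73.5 +/- 12.5 y, weight 58.7 +/- 14.1 kg, serum creatinine
#' 151.1 +/- 83.1 µmol/L, 63.4% male, 2.3 +/- 1.3 troughs (clipped 1-5).
#'
#' @param ... Overrides passed to [cohort_spec()].
#' @return An object of class `cohort_spec`.
#' @export
validation_cohort_spec <- function(...) {
  defaults <- list(n_subjects = 112, age_mean = 73.5, age_sd = 12.5,
                   tbw_mean = 58.7, tbw_sd = 14.1,
                   scr_mean = 151.1, scr_sd = 83.1,
                   male_fraction = 0.634,
                   samples_mean = 2.3, samples_sd = 1.3,
                   samples_range = c(1, 5))
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_spec, args)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Cohort spec: n=%d, age %.1f+/-%.1f [%g,%g] y, TBW %.1f+/-%.1f [%g,%g] kg,\n  SCr %.1f+/-%.1f umol/L, male %.1f%%, %.1f+/-%.1f troughs [%g,%g], horizon %g h%s\n",
    x$n_subjects, x$age_mean, x$age_sd, x$age_range[1], x$age_range[2],
    x$tbw_mean, x$tbw_sd, x$tbw_range[1], x$tbw_range[2],
    x$scr_mean, x$scr_sd, 100 * x$male_fraction,
    x$samples_mean, x$samples_sd, x$samples_range[1], x$samples_range[2],
    x$horizon, if (x$ckd_only) ", CKD-only (CrCl < 60)" else ""))
  invisible(x)
}

rtruncnorm1 <- function(mean, sd, lower, upper, max_tries = 10000) {
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop("truncation bounds [", lower, ", ", upper,
       "] are infeasible for mean ", mean, ", sd ", sd, call. = FALSE)
}

# one subject's covariates, honouring truncation and the CKD-only filter
draw_covariates <- function(spec, max_tries = 10000) {
  for (i in seq_len(max_tries)) {
    age <- rtruncnorm1(spec$age_mean, spec$age_sd, spec$age_range[1],
                       spec$age_range[2])
    tbw <- rtruncnorm1(spec$tbw_mean, spec$tbw_sd, spec$tbw_range[1],
                       spec$tbw_range[2])
    scr <- rtruncnorm1(spec$scr_mean, spec$scr_sd, spec$scr_min, Inf)
    sex <- if (stats::runif(1) < spec$male_fraction) "male" else "female"
    cov <- patient_covariates(age, sex, tbw, scr)
    if (!spec$ckd_only || cockcroft_gault(cov) < 60) return(cov)
  }
  stop("could not draw a subject with CrCl < 60 under the given covariate ",
       "distributions", call. = FALSE)
}

# protocol dosing for one subject: 15-20 mg/kg rounded to the grid,
# q12h if CrCl >= cutoff else q24h, per-infusion and rate caps
protocol_regimen <- function(cov, spec) {
  per_kg <- stats::runif(1, spec$dose_per_kg_range[1],
                         spec$dose_per_kg_range[2])
  amount <- round(per_kg * cov$tbw / spec$dose_rounding) * spec$dose_rounding
  amount <- min(max(amount, spec$dose_rounding), spec$max_dose)
  interval <- if (cockcroft_gault(cov) >= spec$interval_crcl_cutoff) 12 else 24
  list(regimen = regimen(maintenance_dose = amount, interval = interval),
       dose_per_kg_target = per_kg)
}

draw_sample_times <- function(doses, spec) {
  n <- round(stats::rnorm(1, spec$samples_mean, spec$samples_sd))
  n <- min(max(n, spec$samples_range[1]), spec$samples_range[2])
  # troughs sit 0-1 h before a scheduled dose (never the first dose)
  cand <- doses$time[doses$time > 0 & doses$time <= spec$horizon]
  if (length(cand) == 0) cand <- spec$horizon
  picked <- sort(sample(cand, min(n, length(cand))))
  pmax(picked - stats::runif(length(picked), 0, 1), 0)
}

#' Generate a synthetic CKD cohort
#'
#' Draws covariates, protocol dosing histories and sparse trough sampling
#' times for `spec$n_subjects` subjects.  Concentrations are not simulated
#' here; pass the cohort to [simulate_cohort()] for that.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; generation is a pure function of
#'   `(spec, seed)`.
#' @return An object of class `pk_cohort`: a list of subjects, each with
#'   `id`, `cov`, `doses`, `sample_times`, `dose_per_kg_target` and an
#'   (initially empty) named numeric vector `extra` of additional
#'   covariates.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    subjects <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      cov <- draw_covariates(spec)
      pr <- protocol_regimen(cov, spec)
      doses <- expand_regimen(pr$regimen, spec$horizon,
                              max_rate = spec$max_rate)
      subjects[[i]] <- list(
        id = as.character(i), cov = cov, doses = doses,
        sample_times = draw_sample_times(doses, spec),
        dose_per_kg_target = pr$dose_per_kg_target,
        extra = stats::setNames(numeric(0), character(0)))
    }
    structure(subjects, class = "pk_cohort", spec = spec)
  })
}

#' Generate a synthetic validation cohort
#'
#' [generate_cohort()] under [validation_cohort_spec()] defaults.
#'
#' @param spec A [cohort_spec()]; defaults to [validation_cohort_spec()].
#' @param seed Integer seed.
#' @return A `pk_cohort`.
#' @export
generate_validation_cohort <- function(spec = validation_cohort_spec(),
                                       seed = NULL) {
  generate_cohort(spec, seed)
}

#' @export
print.pk_cohort <- function(x, ...) {
  ages <- vapply(x, function(s) s$cov$age, numeric(1))
  crcl <- vapply(x, function(s) cockcroft_gault(s$cov), numeric(1))
  nobs <- vapply(x, function(s) length(s$sample_times), numeric(1))
  cat(sprintf(
    "Synthetic cohort: %d subjects, age %.1f+/-%.1f y, CrCl %.1f+/-%.1f ml/min, %.2f troughs/subject\n",
    length(x), mean(ages), stats::sd(ages), mean(crcl), stats::sd(crcl),
    mean(nobs)))
  invisible(x)
}

#' Attach a noise covariate to every subject of a cohort
#'
#' Adds an extra subject-level covariate column (for example a standard-
#' normal noise covariate used to study covariate-selection specificity).
#'
#' @param cohort A `pk_cohort`.
#' @param name Covariate name.
#' @param values Numeric vector, one per subject; if `NULL`, standard-normal
#'   draws under `seed`.
#' @param seed Integer seed used when `values` is `NULL`.
#' @return The cohort with `extra[[name]]` set on every subject.
#' @export
add_cohort_covariate <- function(cohort, name, values = NULL, seed = NULL) {
  if (is.null(values)) {
    values <- with_seed(seed, stats::rnorm(length(cohort)))
  }
  stopifnot(length(values) == length(cohort))
  for (i in seq_along(cohort)) {
    cohort[[i]]$extra[[name]] <- values[i]
  }
  cohort
}
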
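# Shared fixtures, built in code.

# serum creatinine (µmol/L) that gives a target CG CrCl for a male patient
scr_for_crcl <- function(crcl, age, tbw) {
  88.42 * (140 - age) * tbw / (72 * crcl)
}

# the reference patient: typical derivation-cohort male with CrCl 33.8
ref_patient <- function() {
  patient_covariates(age = 72, sex = "male", tbw = 57.8,
                     scr = scr_for_crcl(33.8, 72, 57.8))
}

# individual with the published typical parameters (CL 1.30 L/h, V 71.094 L)
ref_individual <- function() {
  individual_parameters(ref_patient(), 0, 0, population_parameters())
}

# simulated analysis-ready dataset from the final model
make_fit_data <- function(n_subjects, seed, pop = population_parameters(),
                          samples_mean = 2.1, samples_sd = 1.3,
                          samples_range = c(1, 4)) {
  spec <- cohort_spec(n_subjects = n_subjects, samples_mean = samples_mean,
                      samples_sd = samples_sd,
                      samples_range = samples_range)
  coh <- generate_cohort(spec, seed = seed)
  recs <- simulate_cohort(coh, pop, seed = seed + 1)
  structure(as_pk_data(coh, recs), true_etas = attr(recs, "etas"),
            cohort = coh)
}

# memoised heavyweight fixtures shared across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the recovery-scale fit: 200 subjects, ~3 troughs each, final-model truth
recovery_fit <- function() {
  cached("recovery_fit", {
    dat <- make_fit_data(200, seed = 20260101, samples_mean = 3)
    fit_population(dat, n_starts = 1, compute_se = FALSE, seed = 1)
  })
}
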
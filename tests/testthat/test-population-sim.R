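test_that("eta sampling honours the variance parameters and the seed contract", {
  pop <- population_parameters()
  none <- population_parameters(omega_cl = 0, omega_v = 0)
  e0 <- sample_etas(50, none, seed = 1)
  expect_true(all(e0$eta_cl == 0) && all(e0$eta_v == 0))
  e1 <- sample_etas(10000, pop, seed = 2)
  expect_equal(sd(e1$eta_cl), 0.544, tolerance = 0.02 / 0.544)
  expect_equal(sd(e1$eta_v), 0.225, tolerance = 0.02 / 0.225)
  expect_identical(sample_etas(100, pop, seed = 7),
                   sample_etas(100, pop, seed = 7))
  # draws leave the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_etas(5, pop, seed = 3))
  expect_identical(runif(1), before)
})

test_that("residual error reduces to identity without noise and truncates at zero", {
  none <- population_parameters(sigma_add = 0, sigma_prop2 = 0)
  pred <- c(0, 1.7, 25.3)
  expect_equal(as.numeric(apply_residual_error(pred, none, seed = 1)), pred)
  # pred = 0: symmetric additive noise truncated at zero -> half the draws are 0
  pop <- population_parameters()
  obs <- apply_residual_error(rep(0, 1e5), pop, seed = 4)
  expect_equal(mean(obs == 0), 0.5, tolerance = 0.01 / 0.5)
  expect_true(all(obs >= 0))
  expect_equal(attr(obs, "n_truncated"), sum(obs == 0))
})

test_that("residual variance follows sigma_add^2 + pred^2 sigma_prop2", {
  pop <- population_parameters(sigma_add = 1.5, sigma_prop2 = 0.04)
  pred <- rep(40, 2e5)  # proportional term dominates: 64 vs 2.25
  obs <- apply_residual_error(pred, pop, seed = 5)
  expect_equal(var(as.numeric(obs)), 40^2 * 0.04 + 1.5^2,
               tolerance = 0.05)
})

test_that("subject simulation is deterministic and collapses to the PK core without variability", {
  cov <- ref_patient()
  doses <- expand_regimen(regimen(1000, 24), 120)
  tt <- c(23.5, 47.5, 95.5)
  none <- population_parameters(omega_cl = 0, omega_v = 0, sigma_add = 0,
                                sigma_prop2 = 0)
  sim <- simulate_subject(cov, doses, tt, none, seed = 1)
  expect_equal(sim$value,
               concentration(tt, doses, ref_individual()),
               tolerance = 1e-12)
  pop <- population_parameters()
  a <- simulate_subject(cov, doses, tt, pop, seed = 42)
  b <- simulate_subject(cov, doses, tt, pop, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$value,
                         simulate_subject(cov, doses, tt, pop,
                                          seed = 43)$value))
})

test_that("simulated steady-state troughs cluster around the closed-form trough", {
  cov <- ref_patient()
  reg <- regimen(1000, 24)
  doses <- expand_regimen(reg, 24 * 60)
  # at fixed etas = 0 the only noise is residual error
  pop <- population_parameters(omega_cl = 0, omega_v = 0)
  css <- steady_state_trough(reg, ref_individual())
  tt <- rep(24 * 60, 400)
  sim <- simulate_subject(cov, doses, tt, pop, seed = 9)
  expect_equal(mean(sim$value), css, tolerance = 3 * 2.46 / sqrt(400) / css)
  expect_lt(abs(sd(sim$value) - sqrt(2.46^2 + css^2 * 0.001)), 0.35)
})

test_that("VPC is calibrated on self-simulated data and degenerates sensibly", {
  pop <- population_parameters()
  spec <- cohort_spec(n_subjects = 40)
  for (master in c(101, 202, 303)) {
    coh <- generate_cohort(spec, seed = master)
    obs <- simulate_cohort(coh, pop, seed = master + 1)
    v <- vpc(obs[, c("subject_id", "time", "value")], coh, pop,
             n_replicates = 100, seed = master + 2)
    expect_gte(vpc_fraction_within(v), 0.90)
  }
  # one replicate: bands collapse onto that replicate's percentiles
  coh <- generate_cohort(spec, seed = 1)
  obs <- simulate_cohort(coh, pop, seed = 2)
  v1 <- vpc(obs, coh, pop, n_replicates = 1, seed = 3)
  expect_equal(v1$band_lower, v1$band_upper, tolerance = 1e-12)
})

test_that("VPC detects gross dose misspecification", {
  pop <- population_parameters()
  spec <- cohort_spec(n_subjects = 40)
  coh <- generate_cohort(spec, seed = 11)
  obs <- simulate_cohort(coh, pop, seed = 12)
  # simulate under doubled doses: observed medians should fall below the band
  coh2 <- coh
  for (i in seq_along(coh2)) coh2[[i]]$doses$amount <-
      2 * coh2[[i]]$doses$amount
  for (i in seq_along(coh2)) coh2[[i]]$doses$rate <-
      2 * coh2[[i]]$doses$rate
  v <- vpc(obs, coh2, pop, n_replicates = 100, seed = 13)
  med_obs <- v$observed_percentiles[, "p50"]
  med_lo <- v$band_lower[, "p50"]
  expect_true(mean(med_obs < med_lo, na.rm = TRUE) >= 0.75)
})

test_that("zero-variance population makes the whole stochastic layer deterministic", {
  none <- population_parameters(omega_cl = 0, omega_v = 0, sigma_add = 0,
                                sigma_prop2 = 0)
  coh <- generate_cohort(cohort_spec(n_subjects = 5), seed = 3)
  a <- simulate_cohort(coh, none, seed = 1)
  b <- simulate_cohort(coh, none, seed = 999)
  expect_equal(a$value, b$value, tolerance = 1e-12)
  nf <- simulate_cohort(coh, population_parameters(), seed = 1,
                        noise_free = TRUE)
  for (i in seq_along(coh)) {
    s <- coh[[i]]
    expect_equal(nf$value[nf$subject_id == s$id],
                 concentration(s$sample_times, s$doses,
                               individual_parameters(s$cov, 0, 0)),
                 tolerance = 1e-12)
  }
})
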
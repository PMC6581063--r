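test_that("Cockcroft-Gault matches hand-evaluated values and scales as expected", {
  male <- patient_covariates(40, "male", 72, 88.42)
  expect_equal(cockcroft_gault(male), 100.0, tolerance = 1e-12)
  female <- patient_covariates(40, "female", 72, 88.42)
  expect_equal(cockcroft_gault(female), 85.0, tolerance = 1e-12)
  # inversely proportional to serum creatinine
  doubled <- patient_covariates(40, "male", 72, 2 * 88.42)
  expect_equal(cockcroft_gault(doubled), 50.0, tolerance = 1e-12)
})

test_that("covariate domain errors name the offending field", {
  expect_error(patient_covariates(-1, "male", 70, 100), "age")
  expect_error(patient_covariates(50, "male", 0, 100), "tbw")
  expect_error(patient_covariates(50, "male", 70, -5), "scr")
  expect_error(cockcroft_gault(patient_covariates(140.5, "male", 70, 100)),
               "age")
  expect_error(patient_covariates(50, "dog", 70, 100))
})

test_that("typical clearance is the centred linear model with exact reference identity", {
  pop <- population_parameters()
  expect_identical(typical_clearance(33.8, pop), 1.30)
  expect_equal(typical_clearance(43.8, pop), 1.53, tolerance = 1e-12)
  # zero slope: flat in CrCl
  flat <- population_parameters(theta_crcl = 0)
  for (crcl in c(5, 33.8, 90)) {
    expect_identical(typical_clearance(crcl, flat), 1.30)
  }
  # strictly increasing in CrCl for positive slope
  grid <- seq(5, 100, by = 5)
  cl <- vapply(grid, typical_clearance, numeric(1), pop = pop)
  expect_true(all(diff(cl) > 0))
  expect_error(typical_clearance(0, pop), "crcl")
})

test_that("the clearance floor keeps clearance positive at extreme low CrCl", {
  pop <- population_parameters(theta_crcl = 0.1)
  # uncentred value would be 1.30 + 0.1 * (1 - 33.8) < 0
  expect_equal(typical_clearance(1, pop), pop$cl_floor)
})

test_that("individual parameters follow the exponential-IIV construction", {
  pop <- population_parameters()
  ind <- ref_individual()
  expect_equal(ind$cl, 1.30, tolerance = 1e-12)
  expect_equal(ind$v, 1.23 * 57.8, tolerance = 1e-12)  # 71.094 L
  # eta_cl = ln 2 doubles clearance
  ind2 <- individual_parameters(ref_patient(), log(2), 0, pop)
  expect_equal(ind2$cl, 2 * ind$cl, tolerance = 1e-12)
  # doubling weight doubles volume at eta_v = 0
  heavy <- patient_covariates(72, "male", 2 * 57.8,
                              scr_for_crcl(33.8, 72, 57.8))
  ind3 <- individual_parameters(heavy, 0, 0, pop)
  expect_equal(ind3$v, 2 * ind$v, tolerance = 1e-12)
  # positivity for extreme etas
  ind4 <- individual_parameters(ref_patient(), -10, -10, pop)
  expect_gt(ind4$cl, 0)
  expect_gt(ind4$v, 0)
  expect_gt(ind4$k, 0)
})

test_that("dose event validation rejects boluses, unsorted and overlapping histories", {
  expect_error(dose_events(0, 1000, 0), "bolus")
  expect_error(dose_events(c(10, 0), c(500, 500), c(1, 1)), "sorted")
  expect_error(dose_events(c(0, 1), c(1000, 1000), c(2, 2)), "overlap")
  d <- dose_events(c(0, 12), c(1000, 750))
  expect_equal(d$duration, c(2, 1.5))  # 500 mg/h cap
  expect_equal(d$rate, c(500, 500))
  expect_equal(default_infusion_duration(250), 1)  # 1 h minimum
})

test_that("no drug has appeared before the first infusion starts", {
  ind <- ref_individual()
  d <- dose_events(c(0, 24), c(1000, 1000), c(2, 2))
  expect_identical(concentration(0, d, ind), 0)
  expect_identical(concentration(c(0, 0), d, ind), c(0, 0))
})

test_that("closed-form concentration matches adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  ind <- ref_individual()
  d <- dose_events(c(0, 12, 24), c(1000, 750, 750), c(2, 1.5, 1.5))
  tt <- c(1, 2, 5, 12.5, 13.5, 20, 25, 40)
  closed <- concentration(tt, d, ind)
  rate_at <- function(t) {
    sum(d$rate[t >= d$time & t < d$time + d$duration])
  }
  ode <- deSolve::ode(
    y = c(C = 0), times = c(0, tt),
    func = function(t, y, p) list(rate_at(t) / ind$v - (ind$cl / ind$v) * y),
    parms = NULL, rtol = 1e-10, atol = 1e-12, hmax = 0.05)
  expect_equal(closed, unname(ode[-1, "C"]), tolerance = 1e-6)
})

test_that("concentration is homogeneous of degree 1 in dose amounts", {
  ind <- ref_individual()
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    times <- sort(runif(n, 0, 100))
    times <- times + c(0, cumsum(rep(3, n - 1)))  # enforce spacing > duration
    amt <- runif(n, 250, 2000)
    d <- dose_events(times, amt, rep(1.5, n))
    d2 <- dose_events(times, 3 * amt, rep(1.5, n))
    tt <- runif(5, 0, 150)
    expect_equal(concentration(tt, d2, ind),
                 3 * concentration(tt, d, ind), tolerance = 1e-12)
  }
})

test_that("steady-state trough agrees with long-run superposition", {
  ind <- ref_individual()
  reg <- regimen(1000, 24)
  css <- steady_state_trough(reg, ind)
  d <- expand_regimen(reg, 24 * 50)
  expect_equal(concentration(24 * 50, d, ind), css, tolerance = 1e-6)
  # linear PK: doubling the maintenance dose doubles the trough
  # (250 and 500 mg share the same 1 h infusion under the rate rule,
  # isolating pure dose linearity)
  css_250 <- steady_state_trough(regimen(250, 24), ind)
  css_500 <- steady_state_trough(regimen(500, 24), ind)
  expect_equal(css_500, 2 * css_250, tolerance = 1e-12)
  # accumulation ratio -> 1 when the interval dwarfs the half-life
  fast <- list(cl = 30, v = 30)  # t1/2 ~ 0.7 h
  regf <- regimen(1000, 48)
  single <- concentration(48, dose_events(0, 1000, 2), fast)
  expect_equal(steady_state_trough(regf, fast), single, tolerance = 1e-6)
  expect_error(steady_state_trough(regimen(1000, 1.5), ind), "interval")
})

test_that("steady-state trough falls as clearance rises", {
  reg <- regimen(1000, 24)
  cls <- seq(0.5, 4, by = 0.25)
  troughs <- vapply(cls, function(cl)
    steady_state_trough(reg, list(cl = cl, v = 71.094)), numeric(1))
  expect_true(all(diff(troughs) < 0))
})

test_that("regimen expansion yields increasing non-overlapping infusions", {
  reg <- regimen(1000, 12, loading_dose = 1500)
  d <- expand_regimen(reg, 72)
  expect_true(all(diff(d$time) > 0))
  expect_true(all(d$time[-1] >= (d$time + d$duration)[-nrow(d)]))
  expect_equal(d$amount[1], 1500)
  expect_equal(unique(d$amount[-1]), 1000)
  # no loading: first dose at time zero
  d0 <- expand_regimen(regimen(750, 24), 72)
  expect_equal(d0$time, c(0, 24, 48, 72))
})
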
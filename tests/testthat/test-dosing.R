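test_that("initial recommendation hits the window for the typical derivation patient", {
  recs <- recommend_initial(ref_patient(), target_window(15, 20))
  expect_gt(nrow(recs), 0)
  top <- recs[1, ]
  reg <- regimen(top$maintenance_dose, top$interval, top$loading_dose)
  # closed-form cross-check of the reported steady-state trough
  css <- steady_state_trough(reg, ref_individual())
  expect_equal(top$predicted_ss_trough, css, tolerance = 1e-12)
  expect_gte(css, 15); expect_lte(css, 20)
  expect_true(all(recs$within_constraints))
})

test_that("no emitted regimen ever violates the safety constraints", {
  cn <- dosing_constraints()
  set.seed(41)
  for (i in 1:25) {
    cov <- patient_covariates(runif(1, 31, 97), sample(c("male", "female"), 1),
                              runif(1, 33.6, 103.8), runif(1, 60, 400))
    recs <- suppressWarnings(
      recommend_initial(cov, target_window(15, 20), constraints = cn))
    if (nrow(recs) == 0) next
    expect_true(all(recs$maintenance_dose <=
                      min(cn$max_maintenance_per_kg * cov$tbw,
                          cn$max_dose_per_infusion) + 1e-9))
    expect_true(all(recs$loading_dose <=
                      min(cn$max_loading_per_kg * cov$tbw,
                          cn$max_dose_per_infusion) + 1e-9))
    expect_true(all(recs$maintenance_dose %% cn$dose_rounding == 0))
    expect_true(all(recs$interval %in% cn$allowed_intervals))
  }
})

test_that("an unattainably narrow window yields an empty, explained result", {
  out <- recommend_initial(ref_patient(), target_window(15, 15.01))
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "explanation"), "no regimen")
})

test_that("a CrCl at or above 60 warns but still recommends", {
  healthy <- patient_covariates(40, "male", 80, 70)
  expect_warning(recommend_initial(healthy, target_window(10, 15)),
                 "CrCl")
})

test_that("loading never delays target attainment for the top recommendation", {
  set.seed(42)
  for (i in 1:10) {
    cov <- patient_covariates(runif(1, 40, 95), "male",
                              runif(1, 40, 100),
                              scr_for_crcl(runif(1, 15, 55), 70, 60))
    recs <- suppressWarnings(recommend_initial(cov, target_window(15, 20),
                                               use_loading = TRUE))
    if (nrow(recs) == 0) next
    no_load <- recs[recs$loading_dose == 0, , drop = FALSE]
    expect_lte(recs$time_to_window[1], no_load$time_to_window[1])
  }
})

test_that("a trough confirming the prediction keeps the current regimen on top", {
  cov <- ref_patient()
  recs <- recommend_initial(cov, target_window(15, 20), use_loading = FALSE)
  top <- recs[1, ]
  reg <- regimen(top$maintenance_dose, top$interval)
  doses <- expand_regimen(reg, 24 * 12)
  tt <- max(doses$time)
  obs <- data.frame(time = tt,
                    value = concentration(tt, doses, ref_individual()))
  adj <- adjust_regimen(cov, doses, obs, target_window(15, 20))
  expect_equal(adj$recommendations$maintenance_dose[1], top$maintenance_dose)
  expect_equal(adj$recommendations$interval[1], top$interval)
  expect_equal(adj$hold_hours, 0)
})

test_that("an unexpectedly high trough lowers the recommended daily dose", {
  cov <- ref_patient()
  init_recs <- recommend_initial(cov, target_window(15, 20),
                                 use_loading = FALSE)
  top <- init_recs[1, ]
  doses <- expand_regimen(regimen(top$maintenance_dose, top$interval),
                          24 * 12)
  tt <- max(doses$time)
  pred <- concentration(tt, doses, ref_individual())
  obs <- data.frame(time = tt, value = 2 * pred)
  adj <- adjust_regimen(cov, doses, obs, target_window(15, 20))
  expect_lt(adj$individual$cl, 1.30)
  expect_lt(adj$recommendations$daily_dose[1], top$daily_dose)
})

test_that("supratherapeutic troughs trigger a hold that decays below the upper bound", {
  cov <- ref_patient()
  doses <- expand_regimen(regimen(1500, 24), 72)
  obs <- data.frame(time = 71.5, value = 30)
  adj <- adjust_regimen(cov, doses, obs, target_window(15, 20))
  expect_gt(adj$hold_hours, 0)
  expect_equal(adj$hold_hours %% 6, 0)
  expect_lte(concentration(71.5 + adj$hold_hours, doses, adj$individual),
             20)
  # the hold is minimal on the 6 h grid
  if (adj$hold_hours > 6) {
    expect_gt(concentration(71.5 + adj$hold_hours - 6, doses,
                            adj$individual), 20)
  }
})

test_that("profile curves wrap the closed-form solution and are continuous", {
  ind <- ref_individual()
  reg <- regimen(1000, 24, loading_dose = 1500)
  pc <- profile_curve(ind, reg, horizon = 96, dt = 0.25)
  doses <- expand_regimen(reg, 96)
  i <- c(5, 100, 200, 380)
  expect_identical(pc$conc[i], concentration(pc$time[i], doses, ind))
  # peaks sit at end of infusion: conc rises during infusion, falls after
  expect_true(all(abs(diff(pc$conc)) < 3))  # no jumps on a 0.25 h grid
  seg <- pc[pc$time >= 24 & pc$time <= 26, ]   # maintenance infusion window
  expect_true(all(diff(seg$conc) > 0))
  seg2 <- pc[pc$time >= 26 & pc$time <= 48, ]
  expect_true(all(diff(seg2$conc) < 0))
})

test_that("predicted steady-state trough falls as renal function improves", {
  reg <- regimen(1000, 24)
  troughs <- vapply(seq(15, 55, by = 10), function(crcl) {
    cov <- patient_covariates(70, "male", 60, scr_for_crcl(crcl, 70, 60))
    steady_state_trough(reg, individual_parameters(cov, 0, 0))
  }, numeric(1))
  expect_true(all(diff(troughs) < 0))
})

test_that("recommendations are a pure function of their inputs", {
  a <- recommend_initial(ref_patient(), target_window(15, 20))
  b <- recommend_initial(ref_patient(), target_window(15, 20))
  expect_identical(a, b)
})
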
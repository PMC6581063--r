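#' Clinical dosing safety constraints
#'
#' The in-house safety envelope the regimen search must respect: caps of
#' 30 mg/kg for loading and 20 mg/kg for maintenance doses, at most 2 g per
#' infusion regardless of body weight, a maximum administration rate of
#' 500 mg/h, and a 250 mg dose-rounding grid.
#'
#' @param max_loading_per_kg Loading-dose cap, mg/kg.
#' @param max_maintenance_per_kg Maintenance-dose cap, mg/kg.
#' @param max_dose_per_infusion Absolute per-infusion cap, mg.
#' @param max_rate Maximum infusion rate, mg/h.
#' @param allowed_intervals Candidate dosing intervals, h.  The in-house
#'   protocol uses 12/24 h; 36 and 48 h are included for severe renal
#'   impairment and can be disabled.
#' @param dose_rounding Rounding grid, mg.
#' @param min_duration Minimum infusion duration, h.
#' @param min_loading_per_kg Lower edge of the loading-dose grid, mg/kg.
#' @return An object of class `dosing_constraints`.
#' @export
dosing_constraints <- function(max_loading_per_kg = 30,
                               max_maintenance_per_kg = 20,
                               max_dose_per_infusion = 2000,
                               max_rate = 500,
                               allowed_intervals = c(12, 24, 36, 48),
                               dose_rounding = 250, min_duration = 1,
                               min_loading_per_kg = 20) {
  stopifnot(max_loading_per_kg > 0, max_maintenance_per_kg > 0,
            max_dose_per_infusion > 0, max_rate > 0, dose_rounding > 0,
            length(allowed_intervals) >= 1, all(allowed_intervals > 0))
  structure(as.list(environment()), class = "dosing_constraints")
}

#' Therapeutic target window
#'
#' A trough target range, e.g. 10-15 or 15-20 mg/L.
#'
#' @param lower,upper Window bounds in mg/L, `0 < lower < upper`.
#' @return An object of class `target_window`.
#' @export
target_window <- function(lower, upper) {
  check_number(lower, "lower", lower = 0, strict_lower = TRUE)
  check_number(upper, "upper", lower = lower, strict_lower = TRUE)
  structure(list(lower = lower, upper = upper), class = "target_window")
}

# pre-dose trough times/values under a regimen for an individual
simulated_troughs <- function(reg, ind, horizon, cn) {
  doses <- expand_regimen(reg, horizon, max_rate = cn$max_rate,
                          min_duration = cn$min_duration)
  tt <- doses$time[doses$time > 0]
  if (length(tt) == 0) return(data.frame(time = numeric(),
                                         value = numeric()))
  data.frame(time = tt, value = concentration(tt, doses, ind))
}

# core regimen enumeration shared by initial dosing and adjustment
recommend_regimens <- function(ind, tbw, target, use_loading, cn,
                               horizon = 168) {
  stopifnot(inherits(target, "target_window"),
            inherits(cn, "dosing_constraints"))
  maint_cap <- min(cn$max_maintenance_per_kg * tbw, cn$max_dose_per_infusion)
  maint_grid <- seq(cn$dose_rounding, maint_cap, by = cn$dose_rounding)
  if (length(maint_grid) == 0) {
    stop("dose-rounding grid is empty under the given constraints ",
         "(cap ", round(maint_cap), " mg < grid step ", cn$dose_rounding,
         " mg)", call. = FALSE)
  }
  load_cap <- min(cn$max_loading_per_kg * tbw, cn$max_dose_per_infusion)
  load_grid <- 0
  if (use_loading) {
    hi <- floor(load_cap / cn$dose_rounding) * cn$dose_rounding
    lo <- ceiling(cn$min_loading_per_kg * tbw / cn$dose_rounding) *
      cn$dose_rounding
    lo <- min(lo, hi)  # heavy patients: per-kg grid start above the cap
    lg <- if (hi >= cn$dose_rounding) seq(lo, hi, by = cn$dose_rounding)
          else numeric(0)
    load_grid <- c(0, lg[lg > 0])
  }
  mid <- (target$lower + target$upper) / 2
  rows <- list()
  for (interval in sort(cn$allowed_intervals)) {
    for (maint in maint_grid) {
      dur <- default_infusion_duration(maint, cn$max_rate, cn$min_duration)
      if (interval <= dur) next
      reg0 <- regimen(maintenance_dose = maint, interval = interval)
      ss <- steady_state_trough(reg0, ind, cn$max_rate, cn$min_duration)
      if (ss < target$lower || ss > target$upper) next
      for (load in load_grid) {
        reg <- if (load > 0) {
          regimen(maintenance_dose = maint, interval = interval,
                  loading_dose = load)
        } else {
          reg0
        }
        tr <- simulated_troughs(reg, ind, horizon, cn)
        inside <- tr$value >= target$lower & tr$value <= target$upper
        ttw <- if (any(inside)) tr$time[which(inside)[1]] else Inf
        first_tr <- if (nrow(tr)) tr$value[1] else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          loading_dose = load, maintenance_dose = maint,
          interval = interval, predicted_ss_trough = ss,
          predicted_trough_at_first_measure = first_tr,
          time_to_window = ttw, daily_dose = maint * 24 / interval,
          score = abs(ss - mid), within_constraints = TRUE)
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(loading_dose = numeric(), maintenance_dose = numeric(),
                      interval = numeric(), predicted_ss_trough = numeric(),
                      predicted_trough_at_first_measure = numeric(),
                      time_to_window = numeric(), daily_dose = numeric(),
                      score = numeric(), within_constraints = logical())
    attr(out, "explanation") <- paste(
      "no regimen on the allowed dose grid attains a steady-state trough",
      sprintf("inside [%g, %g] mg/L under the safety constraints",
              target$lower, target$upper))
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$score, out$time_to_window, out$daily_dose,
                     out$loading_dose), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("dosing_recommendations", "data.frame")
  out
}

#' @export
print.dosing_recommendations <- function(x, n = 5, ...) {
  if (nrow(x) == 0) {
    cat("No feasible regimen:", attr(x, "explanation"), "\n")
    return(invisible(x))
  }
  cat(sprintf("%d feasible regimen(s); top %d:\n", nrow(x),
              min(n, nrow(x))))
  print(as.data.frame(utils::head(x, n)), digits = 4)
  invisible(x)
}

#' Recommend an initial dosing regimen
#'
#' Enumerates maintenance doses on the rounding grid, allowed intervals and
#' loading options, predicts troughs for the typical patient (etas = 0),
#' keeps regimens whose steady-state trough lies inside the target window,
#' and ranks by distance of the predicted steady-state trough from the
#' window midpoint (ties: shorter time-to-window, then lower daily dose,
#' then smaller loading dose).  Every returned regimen respects the safety
#' constraints by construction; an empty result (with an explanation
#' attribute) is returned when no grid regimen can attain the window.
#'
#' @param cov A [patient_covariates()] object.  A warning (not an error) is
#'   issued when the Cockcroft-Gault CrCl is >= 60 ml/min, outside the
#'   population the model was built for.
#' @param target A [target_window()].
#' @param use_loading Include loading-dose options (a no-load option is
#'   always kept among the candidates).
#' @param constraints A [dosing_constraints()].
#' @param pop A [population_parameters()] object.
#' @param horizon Simulation horizon for time-to-window, h.
#' @return A `dosing_recommendations` data frame, best first.
#' @export
recommend_initial <- function(cov, target = target_window(15, 20),
                              use_loading = TRUE,
                              constraints = dosing_constraints(),
                              pop = population_parameters(),
                              horizon = 168) {
  stopifnot(inherits(cov, "patient_covariates"))
  crcl <- cockcroft_gault(cov)
  if (crcl >= 60) {
    warning(sprintf(
      "CrCl %.1f ml/min is >= 60; the model was derived in patients with CrCl < 60",
      crcl))
  }
  ind <- individual_parameters(cov, 0, 0, pop)
  recommend_regimens(ind, cov$tbw, target, use_loading, constraints,
                     horizon)
}

#' Adjust a regimen after measured troughs
#'
#' MAP-individualises the patient from the observed trough(s) under the
#' dose history actually given, re-runs the regimen search with the
#' individual parameters, and — when the predicted concentration at
#' decision time exceeds the window's upper bound — advises how long to
#' withhold dosing: the smallest multiple of 6 h after which the predicted
#' concentration has decayed to at most the upper bound.
#'
#' @param cov A [patient_covariates()] object.
#' @param doses_given Dose-event `data.frame` of doses already administered.
#' @param observed_troughs `data.frame` with `time`, `value` (>= 1 row).
#' @param target A [target_window()].
#' @param constraints A [dosing_constraints()].
#' @param pop A [population_parameters()] object.
#' @param decision_time Time (h) at which the adjustment is made; defaults
#'   to the last observation time.
#' @param horizon Simulation horizon for time-to-window, h.
#' @return A list: `recommendations` (ranked `dosing_recommendations` for
#'   the individualised patient), `individual` (the MAP
#'   [individual_parameters()]), `hold_hours` (0 when no hold is needed),
#'   `predicted_now` (predicted concentration at decision time, mg/L).
#' @export
adjust_regimen <- function(cov, doses_given, observed_troughs,
                           target = target_window(15, 20),
                           constraints = dosing_constraints(),
                           pop = population_parameters(),
                           decision_time = NULL, horizon = 168) {
  stopifnot(nrow(observed_troughs) >= 1)
  ind <- map_estimate(cov, doses_given, observed_troughs, pop)
  if (is.null(decision_time)) decision_time <- max(observed_troughs$time)
  pred_now <- concentration(decision_time, doses_given, ind)
  hold <- 0
  if (pred_now > target$upper) {
    repeat {
      hold <- hold + 6
      if (concentration(decision_time + hold, doses_given, ind) <=
            target$upper) break
      if (hold > 24 * 28) {
        stop("predicted concentration does not decay below the target ",
             "upper bound within 4 weeks; check the inputs", call. = FALSE)
      }
    }
  }
  recs <- recommend_regimens(ind, cov$tbw, target, use_loading = FALSE,
                             constraints, horizon)
  list(recommendations = recs, individual = ind, hold_hours = hold,
       predicted_now = pred_now)
}

#' Dense noise-free concentration profile
#'
#' @param ind An [individual_parameters()] object (use
#'   [individual_parameters()] with etas 0 for a typical patient).
#' @param reg A [regimen()].
#' @param horizon Profile end time, h.
#' @param dt Grid step, h.
#' @param max_rate,min_duration Infusion-duration rule.
#' @return A `data.frame` with columns `time`, `conc`.
#' @export
profile_curve <- function(ind, reg, horizon, dt = 0.25, max_rate = 500,
                          min_duration = 1) {
  check_number(horizon, "horizon", lower = 0, strict_lower = TRUE)
  doses <- expand_regimen(reg, horizon, max_rate, min_duration)
  tt <- seq(0, horizon, by = dt)
  data.frame(time = tt, conc = concentration(tt, doses, ind))
}
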
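#' Prediction-accuracy metrics
#'
#' The standard external-validation metrics on paired observed and
#' predicted concentrations:
#' \deqn{MAE = \frac{1}{n}\sum |Obs - Pred|, \quad
#'       MSE = \frac{1}{n}\sum (Obs - Pred)^2, \quad RMSE = \sqrt{MSE}}
#' \deqn{PE\% = \frac{Obs - Pred}{Obs} \times 100, \quad
#'       MAPE\% = \frac{1}{n}\sum |PE\%|}
#' Pairs with `obs == 0` are excluded from PE%/MAPE% (the division is
#' undefined) with a logged count; MAE/MSE/RMSE keep all pairs.
#'
#' @param obs,pred Numeric vectors of equal nonzero length, mg/L.
#' @return An object of class `accuracy_report` with elements `n`, `mae`,
#'   `mse`, `rmse`, `mape_percent`, `per_pair_pe_percent`,
#'   `n_excluded_from_mape`.
#' @export
accuracy_metrics <- function(obs, pred) {
  if (length(obs) != length(pred) || length(obs) == 0) {
    stop("obs and pred must have equal nonzero length", call. = FALSE)
  }
  err <- obs - pred
  mse <- mean(err^2)
  nz <- obs != 0
  if (any(!nz)) {
    warning(sum(!nz), " pair(s) with obs == 0 excluded from PE%/MAPE%")
  }
  pe <- rep(NA_real_, length(obs))
  pe[nz] <- err[nz] / obs[nz] * 100
  structure(
    list(n = length(obs), mae = mean(abs(err)), mse = mse,
         rmse = sqrt(mse),
         mape_percent = mean(abs(pe[nz])),
         per_pair_pe_percent = pe,
         n_excluded_from_mape = sum(!nz)),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "Accuracy (n=%d): MAE %.3f mg/L, MSE %.3f (mg/L)^2, RMSE %.3f mg/L, MAPE %.2f%%\n",
    x$n, x$mae, x$mse, x$rmse, x$mape_percent))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `obs - pred`: mean, SD (n-1 denominator) and limits of
#' agreement at mean +/- `loa_multiplier` x SD (the conventional "within
#' 2 standard deviations" rule by default).
#'
#' @param obs,pred Numeric vectors of equal length >= 2.
#' @param loa_multiplier Width of the limits of agreement in SDs.
#' @return An object of class `bland_altman` with `mean_difference`,
#'   `sd_difference`, `loa_lower`, `loa_upper`, `fraction_within_loa`, and
#'   plot-ready `pairs` (`average`, `difference`).
#' @export
bland_altman <- function(obs, pred, loa_multiplier = 2) {
  if (length(obs) != length(pred) || length(obs) < 2) {
    stop("obs and pred must have equal length >= 2", call. = FALSE)
  }
  d <- obs - pred
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - loa_multiplier * s
  hi <- m + loa_multiplier * s
  structure(
    list(mean_difference = m, sd_difference = s,
         loa_lower = lo, loa_upper = hi,
         fraction_within_loa = mean(d >= lo & d <= hi),
         loa_multiplier = loa_multiplier,
         pairs = data.frame(average = (obs + pred) / 2, difference = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: mean diff %.3f mg/L, SD %.3f, LoA [%.3f, %.3f] (%.1f%% within)\n",
    x$mean_difference, x$sd_difference, x$loa_lower, x$loa_upper,
    100 * x$fraction_within_loa))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$pairs$average, x$pairs$difference,
                 xlab = "Average of observed and predicted (mg/L)",
                 ylab = "Observed - predicted (mg/L)", pch = 19, ...)
  graphics::abline(h = c(x$loa_lower, x$mean_difference, x$loa_upper),
                   lty = c(2, 1, 2), col = "grey40")
  invisible(x)
}

#' Score a model against a held-out dataset
#'
#' Predicts every observed concentration in the dataset a priori
#' (population predictions, etas = 0, from each subject's own dosing and
#' covariates; set `use_ipred = TRUE` for posterior MAP-individualised
#' predictions instead), then computes the accuracy metrics and the
#' Bland-Altman analysis.  A verdict flag marks MAPE% below the
#' conventional 30% clinical-acceptability bound.
#'
#' @param data A `pk_data` object with observations.
#' @param pop A [population_parameters()] object to score.
#' @param use_ipred Use MAP individual predictions instead of population
#'   predictions.
#' @param mape_acceptable_percent Acceptability bound on MAPE%.
#' @return A list of class `external_validation`: `accuracy`
#'   (`accuracy_report`), `bland_altman`, `acceptable` (flag),
#'   `n_subjects_excluded` (subjects without any dosing history), `pairs`
#'   (per-observation table).
#' @export
external_validate <- function(data, pop = population_parameters(),
                              use_ipred = FALSE,
                              mape_acceptable_percent = 30) {
  stopifnot(inherits(data, "pk_data"))
  rows <- list()
  excluded <- 0L
  for (s in data) {
    if (nrow(s$obs) == 0) next
    if (nrow(s$doses) == 0) {
      excluded <- excluded + 1L
      next
    }
    ind <- if (use_ipred) {
      map_estimate(s$cov, s$doses, data.frame(time = s$obs$time,
                                              value = s$obs$value),
                   pop, as.list(s$extra))
    } else {
      individual_parameters(s$cov, 0, 0, pop, as.list(s$extra))
    }
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = as.character(s$id), time = s$obs$time,
      obs = s$obs$value,
      pred = concentration(s$obs$time, s$doses, ind))
  }
  if (length(rows) == 0) stop("dataset has no usable observations",
                              call. = FALSE)
  if (excluded > 0) {
    message(excluded, " subject(s) without dosing history excluded")
  }
  pairs <- do.call(rbind, rows)
  acc <- accuracy_metrics(pairs$obs, pairs$pred)
  ba <- bland_altman(pairs$obs, pairs$pred)
  structure(
    list(accuracy = acc, bland_altman = ba,
         acceptable = acc$mape_percent < mape_acceptable_percent,
         mape_acceptable_percent = mape_acceptable_percent,
         n_subjects_excluded = excluded, pairs = pairs),
    class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  print(x$accuracy)
  print(x$bland_altman)
  cat(sprintf("MAPE %.2f%% %s the %g%% clinical-acceptability bound\n",
              x$accuracy$mape_percent,
              if (x$acceptable) "is below" else "is NOT below",
              x$mape_acceptable_percent))
  invisible(x)
}
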
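#' Sample inter-individual random effects
#'
#' Draw independent log-scale random effects `eta_cl ~ N(0, omega_cl^2)` and
#' `eta_v ~ N(0, omega_v^2)` for `n` subjects.
#'
#' @param n Number of subjects (>= 1).
#' @param pop A [population_parameters()] object.
#' @param seed Integer seed; the draw is a pure function of `(n, pop, seed)`.
#' @return A `data.frame` with columns `eta_cl`, `eta_v`.
#' @export
sample_etas <- function(n, pop = population_parameters(), seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, data.frame(
    eta_cl = stats::rnorm(n, 0, pop$omega_cl),
    eta_v = stats::rnorm(n, 0, pop$omega_v)
  ))
}

#' Apply the residual-error model
#'
#' Combined proportional + additive error:
#' `obs = pred * (1 + eps_p) + eps_a` with `eps_p ~ N(0, sigma_prop2)` and
#' `eps_a ~ N(0, sigma_add^2)`, truncated at zero (concentrations cannot be
#' negative).  The number of truncations is available via the
#' `"n_truncated"` attribute.
#'
#' @param pred Noise-free predicted concentrations, mg/L (vectorised).
#' @param pop A [population_parameters()] object.
#' @param seed Optional integer seed.
#' @return Perturbed concentrations, mg/L, same length as `pred`.
#' @export
apply_residual_error <- function(pred, pop = population_parameters(),
                                 seed = NULL) {
  stopifnot(all(pred >= 0))
  n <- length(pred)
  obs <- with_seed(seed, {
    eps_p <- stats::rnorm(n, 0, sqrt(pop$sigma_prop2))
    eps_a <- stats::rnorm(n, 0, pop$sigma_add)
    pred * (1 + eps_p) + eps_a
  })
  trunc_n <- sum(obs < 0)
  obs <- pmax(obs, 0)
  attr(obs, "n_truncated") <- trunc_n
  obs
}

#' Simulate one subject's concentration records
#'
#' Draws one `(eta_cl, eta_v)` pair, computes the noise-free profile at the
#' sampling times, and applies residual error to the records flagged as
#' observations.
#'
#' @param cov A [patient_covariates()] object.
#' @param doses Dose-event `data.frame`.
#' @param sample_times Observation times, h (>= 0).
#' @param pop A [population_parameters()] object.
#' @param seed Optional integer seed.
#' @param subject_id Identifier carried into the output.
#' @param noise_free If `TRUE`, skip both the eta draw and the residual
#'   error (returns deterministic typical-subject predictions when combined
#'   with `etas = c(0, 0)`).
#' @param etas Optional fixed `c(eta_cl, eta_v)` to use instead of sampling.
#' @return A `data.frame` of concentration records with columns
#'   `subject_id`, `time`, `value`, `ipred`, `is_observation`; the drawn
#'   etas are attached as the `"etas"` attribute.
#' @export
simulate_subject <- function(cov, doses, sample_times,
                             pop = population_parameters(), seed = NULL,
                             subject_id = "1", noise_free = FALSE,
                             etas = NULL) {
  stopifnot(all(sample_times >= 0))
  with_seed(seed, {
    if (is.null(etas)) {
      etas <- if (noise_free) c(0, 0) else
        as.numeric(sample_etas(1, pop)[1, ])
    }
    ind <- individual_parameters(cov, etas[1], etas[2], pop)
    ipred <- concentration(sample_times, doses, ind)
    value <- if (noise_free) ipred else
      as.numeric(apply_residual_error(ipred, pop))
    out <- data.frame(subject_id = subject_id, time = sample_times,
                      value = value, ipred = ipred,
                      is_observation = !noise_free)
    attr(out, "etas") <- etas
    out
  })
}

#' Visual predictive check
#'
#' Simulates replicate cohorts under each subject's own dosing and
#' covariates, then compares per-time-bin percentiles of the observed
#' concentrations against the across-replicate band of the same percentiles.
#'
#' @param observed `data.frame` of observed records with columns
#'   `subject_id`, `time`, `value`.
#' @param cohort A cohort as returned by [generate_cohort()] (list of
#'   subjects with `cov`, `doses`, `sample_times`) whose subjects match
#'   `observed`; simulation re-uses each subject's own design.
#' @param pop A [population_parameters()] object to simulate from.
#' @param n_replicates Number of simulation replicates (>= 100 recommended).
#' @param seed Integer seed.
#' @param probs Percentiles summarised per bin.
#' @param n_bins Number of equal-count time bins.
#' @param band Coverage of the across-replicate confidence band.
#' @return An object of class `vpc_summary`.
#' @export
vpc <- function(observed, cohort, pop = population_parameters(),
                n_replicates = 200, seed = NULL,
                probs = c(0.05, 0.5, 0.95), n_bins = 8, band = 0.95) {
  stopifnot(nrow(observed) > 0, n_replicates >= 1)
  # equal-count bins over the pooled observation times
  qs <- unique(stats::quantile(observed$time, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(qs) < 2) qs <- range(observed$time) + c(-0.5, 0.5)
  bins <- cut(observed$time, breaks = qs, include.lowest = TRUE)
  obs_pct <- t(vapply(levels(bins), function(b) {
    v <- observed$value[bins == b]
    if (length(v) == 0) rep(NA_real_, length(probs)) else
      stats::quantile(v, probs, names = FALSE)
  }, numeric(length(probs))))

  seeds <- derive_seeds(seed, n_replicates)
  sim_pct <- array(NA_real_, c(n_replicates, length(levels(bins)),
                               length(probs)))
  for (r in seq_len(n_replicates)) {
    sim <- simulate_cohort(cohort, pop, seed = seeds[r])
    sbins <- cut(sim$time, breaks = qs, include.lowest = TRUE)
    for (bi in seq_along(levels(bins))) {
      v <- sim$value[which(sbins == levels(bins)[bi])]
      if (length(v) > 0) {
        sim_pct[r, bi, ] <- stats::quantile(v, probs, names = FALSE)
      }
    }
  }
  alpha <- (1 - band) / 2
  lower <- apply(sim_pct, c(2, 3), stats::quantile, probs = alpha,
                 na.rm = TRUE)
  upper <- apply(sim_pct, c(2, 3), stats::quantile, probs = 1 - alpha,
                 na.rm = TRUE)
  med <- apply(sim_pct, c(2, 3), stats::median, na.rm = TRUE)
  dimnames(obs_pct) <- dimnames(lower) <- dimnames(upper) <- dimnames(med) <-
    list(levels(bins), paste0("p", probs * 100))
  structure(
    list(bin_edges = qs, probs = probs,
         observed_percentiles = obs_pct,
         band_lower = lower, band_upper = upper, band_median = med,
         n_replicates = n_replicates, n_obs = nrow(observed)),
    class = "vpc_summary"
  )
}

#' @export
print.vpc_summary <- function(x, ...) {
  cat(sprintf("VPC: %d observations, %d bins, %d replicates\n",
              x$n_obs, length(x$bin_edges) - 1, x$n_replicates))
  inside <- vpc_fraction_within(x)
  cat(sprintf("Observed percentile points inside the simulation band: %.1f%%\n",
              100 * inside))
  invisible(x)
}

#' Fraction of observed percentile points inside the VPC band
#'
#' @param x A `vpc_summary`.
#' @return Fraction in `[0, 1]` (NA bins excluded).
#' @export
vpc_fraction_within <- function(x) {
  ok <- !is.na(x$observed_percentiles)
  mean(x$observed_percentiles[ok] >= x$band_lower[ok] - 1e-12 &
         x$observed_percentiles[ok] <= x$band_upper[ok] + 1e-12)
}

#' Plot a visual predictive check
#'
#' @param x A `vpc_summary`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.vpc_summary <- function(x, ...) {
  mids <- (utils::head(x$bin_edges, -1) + utils::tail(x$bin_edges, -1)) / 2
  graphics::matplot(mids, x$band_median, type = "l", lty = 1, col = "grey50",
                    xlab = "Time (h)", ylab = "Concentration (mg/L)", ...)
  for (j in seq_along(x$probs)) {
    graphics::polygon(c(mids, rev(mids)),
                      c(x$band_lower[, j], rev(x$band_upper[, j])),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
  }
  graphics::matpoints(mids, x$observed_percentiles, pch = 19, col = "firebrick")
  invisible(x)
}

#' Simulate a whole cohort once
#'
#' @param cohort List of subjects (`cov`, `doses`, `sample_times`,
#'   optionally `id`) as produced by [generate_cohort()].
#' @param pop A [population_parameters()] object.
#' @param seed Integer seed.
#' @param noise_free Simulate without etas and residual error.
#' @return A `data.frame` of concentration records for all subjects, with a
#'   `data.frame` of the drawn etas in the `"etas"` attribute.
#' @export
simulate_cohort <- function(cohort, pop = population_parameters(),
                            seed = NULL, noise_free = FALSE) {
  seeds <- derive_seeds(seed, length(cohort))
  recs <- vector("list", length(cohort))
  etas <- matrix(0, length(cohort), 2)
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    id <- if (!is.null(s$id)) s$id else as.character(i)
    r <- simulate_subject(s$cov, s$doses, s$sample_times, pop,
                          seed = seeds[i], subject_id = id,
                          noise_free = noise_free)
    etas[i, ] <- attr(r, "etas")
    recs[[i]] <- r
  }
  out <- do.call(rbind, recs)
  attr(out, "etas") <- data.frame(
    subject_id = vapply(seq_along(cohort), function(i)
      if (!is.null(cohort[[i]]$id)) cohort[[i]]$id else as.character(i),
      character(1)),
    eta_cl = etas[, 1], eta_v = etas[, 2])
  out
}
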
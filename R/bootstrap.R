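#' Bootstrap the population fit
#'
#' Subject-level resampling with replacement: each replicate dataset is
#' refit starting from the original estimates, and percentile confidence
#' intervals are formed from the replicate estimates.  Replicates whose fit
#' fails or does not converge are counted and excluded; a result with more
#' than 20% failures is flagged unstable.
#'
#' @param fit A `pk_fit` from [fit_population()] (supplies the data, the
#'   covariate model and the starting values).
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param verbose Progress messages every 25 replicates.
#' @return An object of class `pk_bootstrap`: matrix of replicate
#'   estimates, per-parameter `median`, `lower` (2.5%) and `upper` (97.5%),
#'   `n_failed`, `unstable`.
#' @export
bootstrap_fit <- function(fit, n_replicates = 200, seed = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(fit, "pk_fit"), n_replicates >= 1)
  data <- fit$data
  n <- length(data)
  par_names <- c("tvcl", "theta_crcl", "tvv", "omega_cl", "omega_v",
                 "sigma_add", "sigma_prop2")
  seeds <- derive_seeds(seed, n_replicates)
  est <- matrix(NA_real_, n_replicates, length(par_names),
                dimnames = list(NULL, par_names))
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    idx <- with_seed(seeds[r], sample.int(n, n, replace = TRUE))
    rep_data <- structure(lapply(seq_along(idx), function(j) {
      s <- data[[idx[j]]]
      s$id <- paste0(s$id, ".", j)
      s
    }), class = "pk_data")
    rf <- tryCatch(
      fit_population(rep_data, init = fit$estimates, method = fit$method,
                     cl_covariates = fit$cl_covariates,
                     v_covariates = fit$v_covariates, fixed = fit$fixed,
                     n_starts = 1, compute_se = FALSE, max_iter = 150),
      error = function(e) NULL)
    if (is.null(rf) || !rf$converged) {
      n_failed <- n_failed + 1L
    } else {
      e <- rf$estimates
      est[r, ] <- c(e$tvcl, e$theta_crcl, e$tvv, e$omega_cl, e$omega_v,
                    e$sigma_add, e$sigma_prop2)
    }
    if (verbose && r %% 25 == 0) message("bootstrap replicate ", r, "/",
                                         n_replicates)
  }
  ok <- stats::complete.cases(est)
  qs <- apply(est[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.5, 0.975))
  structure(
    list(estimates = est[ok, , drop = FALSE],
         lower = qs[1, ], median = qs[2, ], upper = qs[3, ],
         n_replicates = n_replicates, n_failed = n_failed,
         unstable = n_failed > 0.2 * n_replicates),
    class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d failed%s)\n", x$n_replicates,
              x$n_failed, if (x$unstable) ", UNSTABLE" else ""))
  print(round(rbind(`2.5%` = x$lower, median = x$median,
                    `97.5%` = x$upper), 4))
  invisible(x)
}
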
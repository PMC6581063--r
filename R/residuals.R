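#' Residual diagnostics: PRED, IPRED, IWRES and CWRES
#'
#' Computes the standard conditional diagnostics from a converged population
#' fit.  `PRED` is the population prediction (all etas 0), `IPRED` the
#' empirical-Bayes individual prediction, `IWRES = (DV - IPRED) / g(IPRED)`
#' the individually weighted residual, and `CWRES` the conditional weighted
#' residual obtained by first-order linearisation of the model about the
#' posterior-mode etas: with `A = df/deta` at the mode,
#' `E = IPRED - A eta_hat`, `Cov = A Omega A' + diag(g^2(IPRED))` and
#' `CWRES = Cov^{-1/2} (DV - E)`.
#'
#' @param fit A `pk_fit` from [fit_population()], or a
#'   [population_parameters()] object (then `data` is required and the
#'   empirical-Bayes etas are computed by [map_estimate()] under that
#'   model).
#' @param data Optional `pk_data`; defaults to the data stored in the fit.
#' @return A `data.frame` with one row per observation: `subject_id`,
#'   `time`, `dv`, `pred`, `ipred`, `iwres`, `cwres`, `flagged` (`TRUE`
#'   where a singular per-subject covariance prevented CWRES computation).
#' @export
compute_cwres <- function(fit, data = NULL) {
  if (inherits(fit, "population_parameters")) {
    if (is.null(data)) {
      stop("data is required when diagnosing a fixed parameter set",
           call. = FALSE)
    }
    pop <- fit
    etas_df <- do.call(rbind, lapply(data, function(s) {
      m <- map_estimate(s$cov, s$doses, s$obs, pop, as.list(s$extra))
      data.frame(subject_id = as.character(s$id), eta_cl = m$eta_cl,
                 eta_v = m$eta_v)
    }))
    fit <- list(estimates = pop, etas = etas_df, converged = TRUE,
                data = data)
  }
  stopifnot(is.list(fit), !is.null(fit$estimates))
  if (!fit$converged) {
    stop("residual diagnostics require a converged fit", call. = FALSE)
  }
  if (is.null(data)) data <- fit$data
  pop <- fit$estimates
  omega <- diag(c(pop$omega_cl^2, pop$omega_v^2), 2)
  out <- vector("list", length(data))
  for (i in seq_along(data)) {
    s <- data[[i]]
    if (nrow(s$obs) == 0) next
    ps <- prep_subject(s)
    clb <- typical_clearance(ps$crcl, pop, as.list(ps$extra))
    w <- typical_volume(ps$tbw, pop, as.list(ps$extra))
    eta <- as.numeric(fit$etas[fit$etas$subject_id == as.character(s$id),
                               c("eta_cl", "eta_v")][1, ])
    if (any(is.na(eta))) eta <- c(0, 0)
    sp <- subject_h_parts(ps, clb, w, eta[1], eta[2],
                          pop$sigma_add^2, pop$sigma_prop2)
    sp0 <- subject_h_parts(ps, clb, w, 0, 0, pop$sigma_add^2,
                           pop$sigma_prop2)
    ipred <- sp$f
    iwres <- (ps$y - ipred) / sqrt(sp$g2)
    A <- sp$F
    covm <- A %*% omega %*% t(A) + diag(sp$g2, ps$n_obs)
    e <- ipred - as.numeric(A %*% eta)
    cw <- rep(NA_real_, ps$n_obs)
    flagged <- FALSE
    L <- tryCatch(t(chol(covm)), error = function(err) NULL)
    if (is.null(L)) {
      flagged <- TRUE
    } else {
      cw <- as.numeric(forwardsolve(L, ps$y - e))
    }
    out[[i]] <- data.frame(subject_id = as.character(s$id),
                           time = s$obs$time, dv = ps$y,
                           pred = sp0$f, ipred = ipred, iwres = iwres,
                           cwres = cw, flagged = flagged)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
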
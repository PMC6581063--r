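#' Stepwise covariate selection
#'
#' Univariate forward selection followed by backward elimination on the
#' approximate -2 log-likelihood.  Forward: at each step, the candidate
#' covariate-parameter pair whose addition drops the objective the most is
#' added if the drop exceeds `forward_dofv`; repeated until no candidate
#' qualifies.  Backward: each selected pair is removed in turn, and any pair
#' whose re-removal raises the objective by less than `backward_dofv` is
#' dropped (smallest increase first).  The default thresholds 3.84 / 6.63
#' are the chi-squared(1) critical values at p = 0.05 and p = 0.01.
#'
#' The CrCl effect on clearance is handled through the model's built-in
#' `theta_crcl` slope (fixed to 0 while unselected); all other candidates
#' enter as centred linear effects.
#'
#' @param data A `pk_data` object.
#' @param candidates List of `c(covariate, parameter)` pairs, with
#'   `parameter` one of `"cl"`, `"v"`; covariates may be `"crcl"`, `"tbw"`,
#'   `"age"`, `"scr"`, `"sex"` or any extra covariate present in the data.
#' @param forward_dofv,backward_dofv Objective-drop thresholds.
#' @param init Starting [population_parameters()]; its `theta_crcl` is the
#'   start value used when the CrCl effect is being tested.
#' @param method,n_starts,max_iter Passed to [fit_population()].
#' @param verbose Log each decision.
#' @return A list: `selected` (character keys `"cov:par"`), `fit` (the
#'   final `pk_fit`), `log` (a `data.frame` decision log).
#' @export
stepwise_covariate_selection <- function(
    data,
    candidates = list(c("crcl", "cl"), c("tbw", "cl"), c("age", "cl"),
                      c("sex", "cl")),
    forward_dofv = 3.84, backward_dofv = 6.63,
    init = population_parameters(), method = "foce_i", n_starts = 1,
    max_iter = 200, verbose = FALSE) {
  stopifnot(inherits(data, "pk_data"))
  keys <- vapply(candidates, function(cd) paste(cd[1], cd[2], sep = ":"),
                 character(1))

  fit_with <- function(selected) {
    has_crcl <- "crcl:cl" %in% selected
    cl_cov <- character(); v_cov <- character()
    for (k in selected) {
      parts <- strsplit(k, ":", fixed = TRUE)[[1]]
      if (k == "crcl:cl") next
      if (parts[2] == "cl") cl_cov <- c(cl_cov, parts[1])
      else v_cov <- c(v_cov, parts[1])
    }
    fixed <- if (has_crcl) NULL else c(theta_crcl = 0)
    fit_population(data, init = init, method = method,
                   cl_covariates = cl_cov, v_covariates = v_cov,
                   fixed = fixed, n_starts = n_starts,
                   compute_se = FALSE, max_iter = max_iter)
  }

  log_rows <- list()
  add_log <- function(phase, action, key, ofv, dofv, accepted) {
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      phase = phase, action = action, candidate = key, ofv = ofv,
      dofv = dofv, accepted = accepted)
  }

  selected <- character(0)
  base_fit <- fit_with(selected)
  current_ofv <- base_fit$objective
  current_fit <- base_fit
  add_log("base", "fit", "", current_ofv, NA, TRUE)

  # forward selection
  remaining <- keys
  repeat {
    if (length(remaining) == 0) break
    trial <- lapply(remaining, function(k) {
      tryCatch(fit_with(c(selected, k)), error = function(e) NULL)
    })
    drops <- vapply(trial, function(f) {
      if (is.null(f) || !f$converged) -Inf else current_ofv - f$objective
    }, numeric(1))
    bi <- which.max(drops)
    for (j in seq_along(remaining)) {
      add_log("forward", "try", remaining[j],
              if (is.null(trial[[j]])) NA else trial[[j]]$objective,
              drops[j], FALSE)
    }
    if (drops[bi] <= forward_dofv) break
    selected <- c(selected, remaining[bi])
    current_fit <- trial[[bi]]
    current_ofv <- current_fit$objective
    add_log("forward", "add", remaining[bi], current_ofv, drops[bi], TRUE)
    vlog(verbose, "forward: added %s (dOFV %.2f)", remaining[bi], drops[bi])
    remaining <- setdiff(remaining, selected)
  }

  # backward elimination
  repeat {
    if (length(selected) == 0) break
    trial <- lapply(selected, function(k) {
      tryCatch(fit_with(setdiff(selected, k)), error = function(e) NULL)
    })
    rises <- vapply(trial, function(f) {
      if (is.null(f) || !f$converged) Inf else f$objective - current_ofv
    }, numeric(1))
    bi <- which.min(rises)
    if (rises[bi] >= backward_dofv) break
    add_log("backward", "remove", selected[bi], trial[[bi]]$objective,
            rises[bi], TRUE)
    vlog(verbose, "backward: removed %s (dOFV %.2f)", selected[bi],
         rises[bi])
    current_fit <- trial[[bi]]
    current_ofv <- current_fit$objective
    selected <- setdiff(selected, selected[bi])
  }

  list(selected = selected, fit = current_fit,
       log = do.call(rbind, log_rows))
}
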
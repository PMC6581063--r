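# ---- likelihood machinery -------------------------------------------------
#
# The marginal likelihood is approximated subject by subject with a Laplace
# approximation about the posterior mode of the random effects.  The inner
# (mode-finding) problem is solved by a damped Newton iteration with an
# analytic gradient and a Gauss-Newton Hessian; "foce_i" uses the
# Gauss-Newton Hessian in the Laplace determinant (residual variance
# evaluated at the individual prediction, i.e. with interaction), while
# "laplace" differentiates the analytic gradient numerically for the full
# Hessian.

# per-subject bundle reused across parameter evaluations
prep_subject <- function(s) {
  obs <- s$obs
  list(id = s$id,
       y = obs$value,
       geom = conc_geometry(obs$time, s$doses),
       crcl = cockcroft_gault(s$cov),
       tbw = s$cov$tbw,
       sex_male = as.numeric(s$cov$sex == "male"),
       age = s$cov$age, scr = s$cov$scr,
       extra = if (is.null(s$extra)) numeric(0) else unlist(s$extra),
       n_obs = nrow(obs))
}

covariate_value <- function(ps, name) {
  switch(name,
         crcl = ps$crcl, tbw = ps$tbw, age = ps$age, scr = ps$scr,
         sex = ps$sex_male,
         {
           v <- ps$extra[[name]]
           if (is.null(v)) stop("unknown covariate '", name, "'",
                                call. = FALSE)
           v
         })
}

# data-part of the penalised objective and its analytic eta-gradient
subject_h_parts <- function(ps, clb, w, e1, e2, sig_a2, sig_p2) {
  cl <- clb * exp(e1)
  v <- w * exp(e2)
  k <- cl / v
  f <- conc_from_geometry(ps$geom, cl, k)
  dfdk <- dconc_dk_from_geometry(ps$geom, cl, k)
  f1 <- -f + k * dfdk          # df/d eta_cl
  f2 <- -k * dfdk              # df/d eta_v
  r <- ps$y - f
  g2 <- pmax(sig_a2 + sig_p2 * f * f, 1e-12)
  hdata <- 0.5 * sum(r * r / g2 + log(2 * pi * g2))
  common <- -r / g2 + sig_p2 * f * (1 / g2 - r * r / (g2 * g2))
  gdata <- c(sum(common * f1), sum(common * f2))
  Fm <- cbind(f1, f2)
  list(h = hdata, g = gdata, f = f, g2 = g2, F = Fm, r = r)
}

# inner MAP problem: damped Newton on h(eta); omega^2 entries of 0 pin the
# corresponding eta at 0
inner_map_fit <- function(ps, clb, w, om2, sig_a2, sig_p2,
                          eta0 = c(0, 0), tol = 1e-7, max_iter = 60) {
  free <- om2 > 0
  eta <- ifelse(free, eta0, 0)
  prior_const <- 0.5 * sum(log(2 * pi * om2[free]))
  h_of <- function(eta) {
    sp <- subject_h_parts(ps, clb, w, eta[1], eta[2], sig_a2, sig_p2)
    sp$h + 0.5 * sum(eta[free]^2 / om2[free]) + prior_const
  }
  sp <- subject_h_parts(ps, clb, w, eta[1], eta[2], sig_a2, sig_p2)
  h <- sp$h + 0.5 * sum(eta[free]^2 / om2[free]) + prior_const
  converged <- !any(free)
  grad_of <- function(eta) {
    spx <- subject_h_parts(ps, clb, w, eta[1], eta[2], sig_a2, sig_p2)
    spx$g + ifelse(free, eta / om2, 0)
  }
  if (any(free)) {
    for (it in seq_len(max_iter)) {
      grad <- sp$g + ifelse(free, eta / om2, 0)
      if (max(abs(grad[free])) < tol) { converged <- TRUE; break }
      if (it <= 8) {
        # Gauss-Newton Hessian: cheap, adequate near-quadratic cases
        W <- 1 / sp$g2
        Hgn <- crossprod(sp$F * sqrt(W)) + diag(1 / pmax(om2, 1e-12), 2)
      } else {
        # GN can zig-zag on very sparse subjects; switch to the exact
        # Hessian by central differences of the analytic gradient
        Hgn <- matrix(0, 2, 2)
        dd <- 1e-5
        for (m in 1:2) {
          ep <- eta; ep[m] <- ep[m] + dd
          em <- eta; em[m] <- em[m] - dd
          Hgn[m, ] <- (grad_of(ep) - grad_of(em)) / (2 * dd)
        }
        Hgn <- (Hgn + t(Hgn)) / 2
        ev <- eigen(Hgn, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < 1e-8) Hgn <- Hgn + diag(1e-8 - min(ev), 2)
      }
      idx <- which(free)
      delta <- rep(0, 2)
      sol <- tryCatch(solve(Hgn[idx, idx, drop = FALSE], -grad[idx]),
                      error = function(e) NULL)
      if (is.null(sol)) break
      delta[idx] <- sol
      step <- 1
      repeat {
        eta_new <- eta + step * delta
        h_new <- h_of(eta_new)
        if (is.finite(h_new) && h_new <= h + 1e-12) break
        step <- step / 2
        if (step < 1e-6) break
      }
      if (step < 1e-6) { converged <- max(abs(grad[free])) < 1e-3; break }
      eta <- eta + step * delta
      sp <- subject_h_parts(ps, clb, w, eta[1], eta[2], sig_a2, sig_p2)
      h <- sp$h + 0.5 * sum(eta[free]^2 / om2[free]) + prior_const
      if (step == 1 && max(abs(delta[idx])) < 1e-9) { converged <- TRUE; break }
    }
  }
  list(eta = eta, h = h, sp = sp, free = free, converged = converged)
}

# Laplace / FOCE-I -2 log marginal likelihood for one subject
subject_nll <- function(ps, clb, w, om2, sig_a2, sig_p2,
                        eta0 = c(0, 0), method = "foce_i") {
  if (ps$n_obs == 0) {
    return(list(nll = 0, eta = c(0, 0), fit = NULL))
  }
  fit <- inner_map_fit(ps, clb, w, om2, sig_a2, sig_p2, eta0)
  free <- fit$free
  p <- sum(free)
  if (p == 0) {
    return(list(nll = 2 * fit$h, eta = fit$eta, fit = fit))
  }
  idx <- which(free)
  if (method == "laplace") {
    # full Hessian by central differences of the analytic gradient
    H <- matrix(0, 2, 2)
    dd <- 1e-4
    for (m in idx) {
      ep <- fit$eta; ep[m] <- ep[m] + dd
      em <- fit$eta; em[m] <- em[m] - dd
      gp <- subject_h_parts(ps, clb, w, ep[1], ep[2], sig_a2, sig_p2)$g +
        ifelse(free, ep / om2, 0)
      gm <- subject_h_parts(ps, clb, w, em[1], em[2], sig_a2, sig_p2)$g +
        ifelse(free, em / om2, 0)
      H[m, ] <- (gp - gm) / (2 * dd)
    }
    H <- (H + t(H)) / 2
  } else {
    W <- 1 / fit$sp$g2
    H <- crossprod(fit$sp$F * sqrt(W)) + diag(ifelse(free, 1 / om2, 0), 2)
  }
  Hf <- H[idx, idx, drop = FALSE]
  detH <- det(Hf)
  if (!is.finite(detH) || detH <= 0) {
    # fall back to the (always PD) Gauss-Newton determinant
    W <- 1 / fit$sp$g2
    Hgn <- crossprod(fit$sp$F * sqrt(W)) + diag(ifelse(free, 1 / om2, 0), 2)
    detH <- det(Hgn[idx, idx, drop = FALSE])
  }
  nll <- 2 * fit$h - p * log(2 * pi) + log(detH)
  list(nll = nll, eta = fit$eta, fit = fit)
}

# ---- parameter packing ----------------------------------------------------

LOG_PARS <- c("tvcl", "tvv", "omega_cl", "omega_v", "sigma_add",
              "sigma_prop2")

theta_names <- function(cl_covariates, v_covariates) {
  c("tvcl", "theta_crcl", "tvv", "omega_cl", "omega_v", "sigma_add",
    "sigma_prop2",
    if (length(cl_covariates)) paste0("beta_cl_", cl_covariates),
    if (length(v_covariates)) paste0("beta_v_", v_covariates))
}

to_transformed <- function(x) {
  out <- x
  for (nm in intersect(names(x), LOG_PARS)) out[nm] <- log(max(x[nm], 1e-10))
  out
}

from_transformed <- function(x) {
  out <- x
  for (nm in intersect(names(x), LOG_PARS)) out[nm] <- exp(x[nm])
  out
}

natural_init <- function(init, cl_covariates, v_covariates) {
  stats::setNames(
    c(init$tvcl, init$theta_crcl, init$tvv, init$omega_cl, init$omega_v,
      init$sigma_add, init$sigma_prop2,
      rep(0, length(cl_covariates)), rep(0, length(v_covariates))),
    theta_names(cl_covariates, v_covariates))
}

pop_from_natural <- function(nat, init, cl_covariates, v_covariates,
                             cov_refs) {
  extra_cl <- list(); extra_v <- list()
  for (nm in cl_covariates) {
    extra_cl[[nm]] <- list(slope = unname(nat[paste0("beta_cl_", nm)]),
                           ref = cov_refs[[nm]])
  }
  for (nm in v_covariates) {
    extra_v[[nm]] <- list(slope = unname(nat[paste0("beta_v_", nm)]),
                          ref = cov_refs[[nm]])
  }
  population_parameters(
    tvcl = unname(nat["tvcl"]), theta_crcl = unname(nat["theta_crcl"]),
    crcl_ref = init$crcl_ref, tvv = unname(nat["tvv"]),
    omega_cl = unname(nat["omega_cl"]), omega_v = unname(nat["omega_v"]),
    sigma_add = unname(nat["sigma_add"]),
    sigma_prop2 = unname(nat["sigma_prop2"]),
    cl_floor = init$cl_floor, extra_cl = extra_cl, extra_v = extra_v)
}

# ---- population fit -------------------------------------------------------

#' Fit the population model by approximate marginal likelihood
#'
#' Maximises a Laplace/FOCE-style approximation of the marginal likelihood
#' over the fixed effects, the two inter-individual variance components and
#' the two residual-error parameters.  The per-subject contribution uses a
#' second-order expansion about the posterior mode of the random effects;
#' with `method = "foce_i"` the residual variance is evaluated at the
#' individual prediction (interaction) and the Gauss-Newton Hessian is used
#' in the Laplace determinant.  Variance parameters are estimated on the log
#' scale, so positivity is structural.
#'
#' @param data A `pk_data` object ([as_pk_data()]): subjects with covariates,
#'   dose histories and observed concentrations.
#' @param init A [population_parameters()] object of starting values (also
#'   fixes `crcl_ref` and `cl_floor`, which are not estimated).
#' @param method `"foce_i"` (default) or `"laplace"`.
#' @param cl_covariates,v_covariates Names of additional linear covariate
#'   effects on clearance / volume-per-kg (beyond the built-in CrCl effect);
#'   used by [stepwise_covariate_selection()].
#' @param fixed Named numeric vector of parameters to hold fixed at the
#'   given (natural-scale) values, e.g. `c(theta_crcl = 0)`.
#' @param n_starts Number of optimisation starts; starts beyond the first
#'   are jittered on the transformed scale to guard against local optima.
#' @param jitter_sd SD of the start jitter (transformed scale).
#' @param seed Seed for the start jitter.
#' @param compute_se Compute relative standard errors from the numerical
#'   Hessian of the objective (adds a modest cost).
#' @param max_iter Outer iteration cap per start.
#' @param engine `"cpp"` (compiled per-subject likelihood, default) or
#'   `"r"` (pure-R reference path; slower, used for cross-checking).
#' @param verbose Emit progress messages.
#' @return An object of class `pk_fit`: estimates
#'   ([population_parameters()]), `objective` (-2 log approximate marginal
#'   likelihood), `rse_percent`, `shrinkage_percent`, `converged`,
#'   `n_subjects`, `n_observations`, per-subject empirical-Bayes etas, and
#'   the prepared data (for residual diagnostics).
#' @export
fit_population <- function(data, init = population_parameters(),
                           method = c("foce_i", "laplace"),
                           cl_covariates = character(),
                           v_covariates = character(),
                           fixed = NULL, n_starts = 3, jitter_sd = 0.2,
                           seed = 1, compute_se = TRUE, max_iter = 300,
                           engine = c("cpp", "r"), verbose = FALSE) {
  engine <- match.arg(engine)
  method <- match.arg(method)
  stopifnot(inherits(data, "pk_data"))
  subs <- lapply(data, prep_subject)
  n_obs_per <- vapply(subs, function(s) s$n_obs, numeric(1))
  if (sum(n_obs_per > 0) < 2) {
    stop("need at least 2 subjects with at least 1 observation each",
         call. = FALSE)
  }
  all_cov <- c(cl_covariates, v_covariates)
  cov_refs <- lapply(stats::setNames(nm = unique(all_cov)), function(nm) {
    mean(vapply(subs, covariate_value, numeric(1), name = nm))
  })

  nat0 <- natural_init(init, cl_covariates, v_covariates)
  fixed_names <- names(fixed)
  if (length(fixed)) nat0[fixed_names] <- fixed
  free_names <- setdiff(names(nat0), fixed_names)
  tr0 <- to_transformed(nat0)

  eta_store <- matrix(0, length(subs), 2)

  # vectorised structural model: typical CL and V-scale per subject
  crcl_vec <- vapply(subs, function(ps) ps$crcl, numeric(1))
  tbw_vec <- vapply(subs, function(ps) ps$tbw, numeric(1))
  Xcl <- if (length(cl_covariates)) {
    vapply(cl_covariates, function(nm)
      vapply(subs, covariate_value, numeric(1), name = nm) - cov_refs[[nm]],
      numeric(length(subs)))
  } else NULL
  Xv <- if (length(v_covariates)) {
    vapply(v_covariates, function(nm)
      vapply(subs, covariate_value, numeric(1), name = nm) - cov_refs[[nm]],
      numeric(length(subs)))
  } else NULL
  structural_vec <- function(nat) {
    clb <- nat[["tvcl"]] + nat[["theta_crcl"]] * (crcl_vec - init$crcl_ref)
    if (!is.null(Xcl)) {
      clb <- clb + drop(Xcl %*% nat[paste0("beta_cl_", cl_covariates)])
    }
    vkg <- rep(nat[["tvv"]], length(subs))
    if (!is.null(Xv)) {
      vkg <- vkg + drop(Xv %*% nat[paste0("beta_v_", v_covariates)])
    }
    list(clb = pmax(clb, init$cl_floor), w = pmax(vkg, 1e-3) * tbw_vec)
  }

  cpp_subs <- lapply(subs, function(ps) {
    g <- ps$geom
    if (ps$n_obs == 0 || g$nd == 0) {
      return(list(y = ps$y, rate = numeric(0),
                  m1 = matrix(0, ps$n_obs, 0), m2 = matrix(0, ps$n_obs, 0),
                  active = matrix(0, ps$n_obs, 0)))
    }
    act <- g$active
    storage.mode(act) <- "double"
    list(y = ps$y, rate = g$rate, m1 = g$m1, m2 = g$m2, active = act)
  })

  objective <- function(free_tr) {
    tr <- tr0
    tr[free_names] <- free_tr
    nat <- from_transformed(tr)
    st <- structural_vec(nat)
    if (engine == "cpp") {
      res <- pop_nll_cpp(cpp_subs, st$clb, st$w,
                         nat[["omega_cl"]]^2, nat[["omega_v"]]^2,
                         nat[["sigma_add"]]^2, nat[["sigma_prop2"]],
                         eta_store, as.integer(method == "laplace"))
      eta_store <<- res$etas
      total <- res$nll
    } else {
      total <- 0
      for (i in seq_along(subs)) {
        ps <- subs[[i]]
        if (ps$n_obs == 0) next
        res <- subject_nll(ps, st$clb[i], st$w[i],
                           c(nat[["omega_cl"]]^2, nat[["omega_v"]]^2),
                           nat[["sigma_add"]]^2, nat[["sigma_prop2"]],
                           eta0 = eta_store[i, ], method = method)
        eta_store[i, ] <<- res$eta
        total <- total + res$nll
      }
    }
    if (!is.finite(total)) total <- 1e10
    total
  }

  start_jitters <- with_seed(seed, lapply(seq_len(n_starts), function(j) {
    if (j == 1) rep(0, length(free_names)) else
      stats::rnorm(length(free_names), 0, jitter_sd)
  }))

  best <- NULL
  obj0 <- objective(tr0[free_names])
  for (j in seq_len(n_starts)) {
    eta_store[] <- 0
    start <- tr0[free_names] + start_jitters[[j]]
    opt <- tryCatch(
      stats::nlminb(start, objective,
                    control = list(iter.max = max_iter,
                                   eval.max = 4 * max_iter,
                                   rel.tol = 1e-9)),
      error = function(e) NULL)
    if (is.null(opt)) next
    vlog(verbose, "start %d: objective %.4f (%s)", j, opt$objective,
         opt$message)
    if (is.null(best) || opt$objective < best$objective - 1e-9) best <- opt
  }
  if (is.null(best)) {
    stop("population fit failed on all starts", call. = FALSE)
  }
  converged <- best$convergence == 0 || best$objective <= obj0 + 1e-6

  tr_hat <- tr0
  tr_hat[free_names] <- best$par
  nat_hat <- from_transformed(tr_hat)
  # final pass at the optimum to refresh the stored EBEs
  eta_store[] <- 0
  final_obj <- objective(best$par)

  est <- pop_from_natural(nat_hat, init, cl_covariates, v_covariates,
                          cov_refs)

  # eta-shrinkage: 1 - SD(EBE)/omega (n-1 denominator)
  use <- n_obs_per > 0
  shr <- c(
    eta_cl = if (nat_hat[["omega_cl"]] > 0)
      (1 - stats::sd(eta_store[use, 1]) / nat_hat[["omega_cl"]]) * 100
    else NA_real_,
    eta_v = if (nat_hat[["omega_v"]] > 0)
      (1 - stats::sd(eta_store[use, 2]) / nat_hat[["omega_v"]]) * 100
    else NA_real_)

  rse <- NULL
  if (compute_se) {
    rse <- tryCatch(
      fit_rse(objective, tr_hat, nat_hat, free_names, final_obj),
      error = function(e) NULL)
  }

  structure(
    list(estimates = est, objective = final_obj,
         rse_percent = rse, shrinkage_percent = shr,
         converged = converged, method = method,
         n_subjects = sum(use), n_observations = sum(n_obs_per),
         etas = data.frame(
           subject_id = vapply(subs, function(s) as.character(s$id),
                               character(1)),
           eta_cl = eta_store[, 1], eta_v = eta_store[, 2],
           n_obs = n_obs_per),
         cl_covariates = cl_covariates, v_covariates = v_covariates,
         fixed = fixed, init = init, data = data,
         message = best$message, initial_objective = obj0),
    class = "pk_fit")
}

# RSE% from the numerical Hessian of the -2LL on the transformed scale,
# delta-method back-transformed to the natural scale
fit_rse <- function(objective, tr_hat, nat_hat, free_names, f0) {
  np <- length(free_names)
  hstep <- 1e-3
  H <- matrix(0, np, np)
  fp <- function(v) objective(v)
  x0 <- tr_hat[free_names]
  fs <- matrix(0, np, 2)
  for (i in seq_len(np)) {
    for (s in c(1, 2)) {
      x <- x0; x[i] <- x[i] + c(hstep, -hstep)[s]
      fs[i, s] <- fp(x)
    }
  }
  for (i in seq_len(np)) {
    H[i, i] <- (fs[i, 1] - 2 * f0 + fs[i, 2]) / hstep^2
    if (i < np) for (j in seq((i + 1), np)) {
      xpp <- x0; xpp[c(i, j)] <- xpp[c(i, j)] + hstep
      xmm <- x0; xmm[c(i, j)] <- xmm[c(i, j)] - hstep
      H[i, j] <- H[j, i] <-
        (fp(xpp) - fs[i, 1] - fs[j, 1] + 2 * f0 - fs[i, 2] - fs[j, 2] +
           fp(xmm)) / (2 * hstep^2)
    }
  }
  # -2LL Hessian: covariance = 2 * H^-1
  cov_tr <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(cov_tr)) return(NULL)
  se_tr <- sqrt(pmax(diag(cov_tr), 0))
  out <- stats::setNames(numeric(length(free_names)), free_names)
  for (i in seq_along(free_names)) {
    nm <- free_names[i]
    if (nm %in% LOG_PARS) {
      # log-scale SE: SE(natural)/natural = SE(log), so RSE% = 100*SE(log)
      out[nm] <- 100 * se_tr[i]
    } else {
      out[nm] <- if (abs(nat_hat[[nm]]) > 0)
        100 * se_tr[i] / abs(nat_hat[[nm]]) else NA_real_
    }
  }
  out
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit (%s): %d subjects, %d observations\n",
              x$method, x$n_subjects, x$n_observations))
  cat(sprintf("  -2LL (approx): %.3f   converged: %s\n", x$objective,
              x$converged))
  e <- x$estimates
  tab <- data.frame(
    estimate = c(e$tvcl, e$theta_crcl, e$tvv, e$omega_cl, e$omega_v,
                 e$sigma_add, e$sigma_prop2),
    row.names = c("tvcl (L/h)", "theta_crcl", "tvv (L/kg)", "omega_cl",
                  "omega_v", "sigma_add (mg/L)", "sigma_prop2"))
  if (!is.null(x$rse_percent)) {
    tab$rse_percent <- NA_real_
    nm_map <- c("tvcl (L/h)" = "tvcl", "theta_crcl" = "theta_crcl",
                "tvv (L/kg)" = "tvv", "omega_cl" = "omega_cl",
                "omega_v" = "omega_v", "sigma_add (mg/L)" = "sigma_add",
                "sigma_prop2" = "sigma_prop2")
    for (rn in rownames(tab)) {
      v <- x$rse_percent[nm_map[rn]]
      if (!is.na(v)) tab[rn, "rse_percent"] <- round(unname(v), 1)
    }
  }
  print(round(tab, 4))
  cat(sprintf("  Shrinkage %%: eta_cl %.1f, eta_v %.1f\n",
              x$shrinkage_percent["eta_cl"], x$shrinkage_percent["eta_v"]))
  invisible(x)
}

#' Evaluate the population objective at fixed parameters
#'
#' Computes the approximate -2 log marginal likelihood of a dataset under a
#' given parameter vector without optimising the population parameters
#' (the per-subject random-effect modes are still found).  Useful for
#' likelihood-ratio comparisons and diagnostics.
#'
#' @param data A `pk_data` object.
#' @param pop A [population_parameters()] object (its `extra_cl`/`extra_v`
#'   effects are honoured).
#' @param method `"foce_i"` or `"laplace"`.
#' @return The objective value (scalar).
#' @export
population_objective <- function(data, pop = population_parameters(),
                                 method = c("foce_i", "laplace")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "pk_data"))
  subs <- lapply(data, prep_subject)
  total <- 0
  for (ps in subs) {
    if (ps$n_obs == 0) next
    clb <- typical_clearance(ps$crcl, pop, as.list(ps$extra))
    w <- typical_volume(ps$tbw, pop, as.list(ps$extra))
    res <- subject_nll(ps, clb, w, c(pop$omega_cl^2, pop$omega_v^2),
                       pop$sigma_add^2, pop$sigma_prop2, method = method)
    total <- total + res$nll
  }
  total
}

# ---- MAP (empirical-Bayes) estimation ------------------------------------

#' MAP-Bayesian individual parameter estimate
#'
#' Finds the posterior mode of the random effects given a subject's dose
#' history and measured concentrations under the population prior:
#' maximises `log p(obs | eta) + log p(eta)`.  With no observations the
#' prior mode `(0, 0)` (the typical patient) is returned.
#'
#' @param cov A [patient_covariates()] object.
#' @param doses Dose-event `data.frame`.
#' @param observations `data.frame` with columns `time` (h) and `value`
#'   (mg/L); may have zero rows.
#' @param pop A [population_parameters()] object.
#' @param extra Optional named extra covariate values.
#' @return An [individual_parameters()] object with attributes
#'   `"converged"` and `"n_obs"`.
#' @export
map_estimate <- function(cov, doses, observations,
                         pop = population_parameters(), extra = NULL) {
  stopifnot(inherits(cov, "patient_covariates"))
  if (is.null(observations) || nrow(observations) == 0) {
    out <- individual_parameters(cov, 0, 0, pop, extra)
    attr(out, "converged") <- TRUE
    attr(out, "n_obs") <- 0L
    return(out)
  }
  s <- list(id = "map", cov = cov, doses = doses,
            obs = data.frame(time = observations$time,
                             value = observations$value),
            extra = extra)
  ps <- prep_subject(s)
  crcl <- cockcroft_gault(cov)
  clb <- typical_clearance(crcl, pop, extra)
  w <- typical_volume(cov$tbw, pop, extra)
  fit <- inner_map_fit(ps, clb, w, c(pop$omega_cl^2, pop$omega_v^2),
                       pop$sigma_add^2, pop$sigma_prop2)
  if (!fit$converged) {
    warning("MAP estimation did not fully converge (gradient ",
            signif(max(abs(fit$sp$g)), 3), "); returning the best mode found")
  }
  out <- individual_parameters(cov, fit$eta[1], fit$eta[2], pop, extra)
  attr(out, "converged") <- fit$converged
  attr(out, "n_obs") <- nrow(observations)
  out
}
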
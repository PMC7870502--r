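# One- and two-compartment IV-bolus disposition models with per-individual
# maximum-likelihood fitting under a proportional or additive residual
# error model, asymptotic precision (CV%), and a precision-based
# 2 -> 1-compartment fallback.
#
# Units throughout: dose mg/kg, volumes mL/kg, clearances mL/min/kg,
# times h, concentrations ug/mL, AUC ng.h/mL. With these units
# C(0) = dose * 1000 / V1 and AUC_inf = dose * 1e6 / (CL * 60).

#' Construct a compartmental parameter set
#'
#' Clearance/volume parameterization of the IV-bolus disposition model:
#' total body clearance `cl_tot` (mL/min/kg), central volume `v1` (mL/kg)
#' and, for the two-compartment model, intercompartmental clearance `q`
#' (mL/min/kg) and peripheral volume `v2` (mL/kg).
#'
#' @param cl_tot Total body clearance (mL/min/kg).
#' @param v1 Central volume of distribution (mL/kg).
#' @param q Intercompartmental clearance (mL/min/kg); `NULL` for 1-comp.
#' @param v2 Peripheral volume (mL/kg); `NULL` for 1-comp.
#' @return An object of class `pk_parameters`.
#' @export
pk_parameters <- function(cl_tot, v1, q = NULL, v2 = NULL) {
  two <- !is.null(q) || !is.null(v2)
  if (two) {
    arc_check(!is.null(q) && !is.null(v2),
              "q and v2 must both be given for a 2-compartment model")
    vals <- c(cl_tot = cl_tot, v1 = v1, q = q, v2 = v2)
  } else {
    vals <- c(cl_tot = cl_tot, v1 = v1)
  }
  arc_check(all(is.finite(vals)) && all(vals > 0),
            "all compartmental parameters must be finite and > 0")
  structure(list(n_compartments = if (two) 2L else 1L,
                 cl_tot = cl_tot, v1 = v1,
                 q = if (two) q else NULL, v2 = if (two) v2 else NULL),
            class = "pk_parameters")
}

# Macro (exponential) constants of the disposition model, rate constants
# in 1/h. For 2-comp: C(t) = A exp(-alpha t) + B exp(-beta t) per unit
# C(0) split; alpha > beta > 0 always holds for positive micro constants.
macro_constants <- function(params, dose) {
  v1 <- params$v1
  c0 <- dose * 1000 / v1
  if (params$n_compartments == 1L) {
    k <- params$cl_tot * 60 / v1
    return(list(coefs = c0, rates = k))
  }
  k10 <- params$cl_tot * 60 / v1
  k12 <- params$q * 60 / v1
  k21 <- params$q * 60 / params$v2
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  a <- c0 * (alpha - k21) / (alpha - beta)
  b <- c0 * (k21 - beta) / (alpha - beta)
  list(coefs = c(a, b), rates = c(alpha, beta))
}

#' Predict plasma concentration after an IV bolus
#'
#' Closed-form mono- or biexponential concentration for the clearance/
#' volume parameterization, \eqn{C(t) = \sum_i A_i e^{-\lambda_i t}} with
#' \eqn{C(0) = D \cdot 1000 / V_1}.
#'
#' @param params A [pk_parameters()] object.
#' @param dose IV bolus dose (mg/kg).
#' @param t Times since dose (h), `t >= 0`.
#' @return Predicted concentrations (ug/mL), same length as `t`.
#' @export
predict_concentration <- function(params, dose, t) {
  arc_check(inherits(params, "pk_parameters"), "params must be pk_parameters")
  arc_check(dose > 0, "dose must be > 0")
  arc_check(all(t >= 0), "times must be >= 0")
  m <- macro_constants(params, dose)
  drop(exp(-outer(t, m$rates)) %*% m$coefs)
}

#' Remove below-LLOQ records from a profile
#'
#' Drops censored (below the lower limit of quantification) records,
#' preserving record order; the fitter receives quantifiable post-dose
#' records only.
#'
#' @param profile A [plasma_profile()].
#' @return The profile without BLQ records.
#' @export
exclude_blq <- function(profile) {
  arc_check(inherits(profile, "plasma_profile"), "not a plasma_profile")
  keep <- !profile$blq
  out <- profile
  out$time <- profile$time[keep]
  out$conc <- profile$conc[keep]
  out$blq <- profile$blq[keep]
  if (n_quantifiable(out) < 3) {
    arc_abort(sprintf(
      "profile %s %s %s: fewer than 3 quantifiable records after BLQ exclusion",
      profile$animal_id, profile$analyte, profile$occasion),
      "arc_insufficient_data_error")
  }
  out
}

# Quantifiable post-dose observations used for fitting.
fit_data <- function(profile) {
  keep <- !profile$blq & profile$time > 0 & !is.na(profile$conc)
  list(t = profile$time[keep], y = profile$conc[keep])
}

# Unchecked closed-form prediction on the natural-parameter vector
# (cl, v1[, q, v2]); hot path for the optimizer, never throws.
pred_ct <- function(v, n_comp, dose, t) {
  c0 <- dose * 1000 / v[2]
  if (n_comp == 1L) return(c0 * exp(-(v[1] * 60 / v[2]) * t))
  k10 <- v[1] * 60 / v[2]
  k12 <- v[3] * 60 / v[2]
  k21 <- v[3] * 60 / v[4]
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  a <- c0 * (alpha - k21) / (alpha - beta)
  b <- c0 * (k21 - beta) / (alpha - beta)
  a * exp(-alpha * t) + b * exp(-beta * t)
}

# Concentrated -2 log-likelihood. Proportional: y = f (1 + eps),
# Var = sigma^2 f^2; additive: y = f + eps, Var = sigma^2. sigma^2 is
# profiled out analytically (ML estimate = mean squared (weighted)
# residual); the floor only guards log(0) in the zero-residual limit.
neg2ll <- function(logpar, t, y, dose, n_comp, error_model) {
  v <- exp(logpar)
  if (any(!is.finite(v)) || any(v <= 0)) return(1e10)
  f <- pred_ct(v, n_comp, dose, t)
  if (any(!is.finite(f)) || any(f <= 0)) return(1e10)
  n <- length(y)
  if (error_model == "proportional") {
    s2 <- mean(((y - f) / f)^2)
    obj <- n * log(max(s2, 1e-30)) + 2 * sum(log(f)) + n * (1 + log(2 * pi))
  } else {
    s2 <- mean((y - f)^2)
    obj <- n * log(max(s2, 1e-30)) + n * (1 + log(2 * pi))
  }
  if (!is.finite(obj)) 1e10 else obj
}

par_from_log <- function(logpar, n_comp) {
  v <- exp(logpar)
  if (n_comp == 1L) pk_parameters(v[1], v[2])
  else pk_parameters(v[1], v[2], v[3], v[4])
}

# Curve stripping (method of residuals): log-linear terminal fit on the
# last up-to-4 quantifiable points gives B/beta; the stripped residuals
# give A/alpha; macro constants are mapped back to CL/V1/Q/V2.
strip_init <- function(t, y, dose, n_comp) {
  loglin <- function(ti, yi) {
    fit <- stats::lm.fit(cbind(1, ti), log(yi))
    cf <- unname(fit$coefficients)
    c(intercept = exp(cf[1]), rate = -cf[2])
  }
  n <- length(t)
  if (n_comp == 1L) {
    f <- loglin(t, y)
    k <- max(f["rate"], 1e-3)
    v1 <- dose * 1000 / max(f["intercept"], 1e-6)
    return(log(c(k * v1 / 60, v1)))
  }
  m <- min(4L, n - 2L)
  tail_idx <- seq.int(n - m + 1L, n)
  ft <- loglin(t[tail_idx], y[tail_idx])
  beta <- max(ft["rate"], 1e-3)
  b <- max(ft["intercept"], 1e-9)
  resid <- y - b * exp(-beta * t)
  head_idx <- setdiff(which(resid > 0 & t < t[tail_idx][1]), tail_idx)
  if (length(head_idx) >= 2) {
    fh <- loglin(t[head_idx], resid[head_idx])
    alpha <- max(fh["rate"], beta * 3)
    a <- max(fh["intercept"], b * 0.1)
  } else {
    alpha <- beta * 5
    a <- max(y[1] - b, b * 0.5)
  }
  c0 <- a + b
  v1 <- dose * 1000 / c0
  k21 <- (a * beta + b * alpha) / c0
  k10 <- alpha * beta / k21
  k12 <- max(alpha + beta - k10 - k21, 1e-4)
  cl <- k10 * v1 / 60
  q <- k12 * v1 / 60
  v2 <- q * 60 / k21
  log(pmax(c(cl, v1, q, v2), 1e-6))
}

# Asymptotic precision from the weighted Gauss-Newton covariance
# sigma^2 (J' W J)^-1 on the log-parameter scale; by the delta method the
# log-scale SE is the relative SE, so CV% = 100 * SE(log theta).
fit_cv_pct <- function(logpar, t, y, dose, n_comp, error_model, sigma2) {
  np <- length(logpar)
  f0 <- pred_ct(exp(logpar), n_comp, dose, t)
  jac <- matrix(0, length(t), np)
  h <- 1e-5
  for (j in seq_len(np)) {
    up <- dn <- logpar
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    jac[, j] <- (pred_ct(exp(up), n_comp, dose, t) -
                 pred_ct(exp(dn), n_comp, dose, t)) / (2 * h)
  }
  w <- if (error_model == "proportional") 1 / f0^2 else rep(1, length(t))
  info <- crossprod(jac * sqrt(w))
  cov <- tryCatch(sigma2 * solve(info), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    return(rep(NA_real_, np))
  }
  100 * sqrt(diag(cov))
}

#' Fit a compartmental model to one profile
#'
#' Per-individual maximum-likelihood fit of the 1- or 2-compartment
#' IV-bolus model under a proportional (`y = f(1 + eps)`) or additive
#' (`y = f + eps`) Gaussian residual error model, `eps ~ N(0, sigma^2)`.
#' The exact -2 log-likelihood (residual variance profiled out) is
#' minimized over log-transformed structural parameters, initialized by
#' curve stripping with jittered multi-start on non-convergence.
#' Parameter precision is reported as CV% from the asymptotic covariance.
#'
#' @param profile A [plasma_profile()]; BLQ and pre-dose records are
#'   excluded automatically.
#' @param n_compartments 1 or 2.
#' @param error_model `"proportional"` or `"additive"`.
#' @param n_starts Number of jittered restarts tried on non-convergence.
#' @return An object of class `compartmental_fit` with elements `params`
#'   ([pk_parameters()]), `error_model`, `sigma`, `cv_pct` (named, one
#'   per structural parameter), `objective` (-2 log-likelihood), `vss`
#'   (mL/kg), `auc_inf` (ng.h/mL), `converged`, and profile metadata.
#' @export
fit_profile <- function(profile, n_compartments = 2L,
                        error_model = c("proportional", "additive"),
                        n_starts = 5L) {
  arc_check(inherits(profile, "plasma_profile"), "not a plasma_profile")
  error_model <- match.arg(error_model)
  n_comp <- as.integer(n_compartments)
  arc_check(n_comp %in% c(1L, 2L), "n_compartments must be 1 or 2")
  d <- fit_data(profile)
  need <- 2L * n_comp + 1L
  if (length(d$t) < need) {
    arc_abort(sprintf(
      "profile %s %s %s: %d quantifiable records, need >= %d for a %d-compartment fit",
      profile$animal_id, profile$analyte, profile$occasion,
      length(d$t), need, n_comp), "arc_insufficient_data_error")
  }
  dose <- profile$dose_mg_per_kg
  init <- strip_init(d$t, d$y, dose, n_comp)

  # Nelder-Mead first (robust against the steep likelihood surface in
  # the near-zero-residual regime), then BFGS polish; a polish that ends
  # up worse than its start (degenerate ridge) is discarded.
  run <- function(start) {
    nm <- stats::optim(start, neg2ll, t = d$t, y = d$y, dose = dose,
                       n_comp = n_comp, error_model = error_model,
                       method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-12))
    bf <- tryCatch(
      stats::optim(nm$par, neg2ll, t = d$t, y = d$y, dose = dose,
                   n_comp = n_comp, error_model = error_model,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12,
                                  ndeps = rep(1e-6, length(start)))),
      error = function(e) NULL)
    if (!is.null(bf) && bf$value <= nm$value) bf else nm
  }
  best <- tryCatch(run(init), error = function(e) NULL)
  ok <- function(o) !is.null(o) && o$convergence == 0 && o$value < 1e9
  if (!ok(best)) {
    for (i in seq_len(n_starts)) {
      # deterministic +/-50% jitter pattern, no RNG draw
      jit <- init + log(1 + 0.5 * sin(i * (seq_along(init) + 1) * 1.7))
      cand <- tryCatch(run(jit), error = function(e) NULL)
      if (ok(cand) && (!ok(best) || cand$value < best$value)) best <- cand
      if (ok(best)) break
    }
  }
  if (is.null(best)) {
    arc_abort(sprintf("profile %s %s %s: optimization failed",
                      profile$animal_id, profile$analyte, profile$occasion),
              "arc_fit_error")
  }
  converged <- ok(best)
  params <- par_from_log(best$par, n_comp)
  f <- predict_concentration(params, dose, d$t)
  sigma2 <- if (error_model == "proportional") {
    mean(((d$y - f) / f)^2)
  } else {
    mean((d$y - f)^2)
  }
  cv <- fit_cv_pct(best$par, d$t, d$y, dose, n_comp, error_model, sigma2)
  names(cv) <- if (n_comp == 1L) c("cl_tot", "v1") else
    c("cl_tot", "v1", "q", "v2")
  vss <- params$v1 + (params$v2 %||% 0)
  structure(
    list(params = params, error_model = error_model,
         sigma = sqrt(sigma2), cv_pct = cv, objective = best$value,
         vss = vss, auc_inf = dose * 1e6 / (params$cl_tot * 60),
         converged = converged, n_obs = length(d$t),
         animal_id = profile$animal_id, analyte = profile$analyte,
         occasion = profile$occasion, group = profile$group,
         dose_mg_per_kg = dose),
    class = "compartmental_fit")
}

#' @export
print.compartmental_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<compartmental_fit> %s %s %s: %d-comp %s error%s\n",
    x$animal_id %||% "?", x$analyte %||% "?", x$occasion %||% "?",
    p$n_compartments, x$error_model,
    if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  CL_TOT %.3f mL/min/kg, V1 %.1f mL/kg", p$cl_tot, p$v1))
  if (p$n_compartments == 2L) {
    cat(sprintf(", Q %.3f mL/min/kg, V2 %.1f mL/kg", p$q, p$v2))
  }
  cat(sprintf("\n  V_ss %.1f mL/kg, AUC_0-inf %.0f ng.h/mL, sigma %.3g\n",
              x$vss, x$auc_inf, x$sigma))
  invisible(x)
}

#' Precision-gated model selection
#'
#' Reproduces the study's model-order policy: fit the analyte's
#' structural model (two compartments, proportional error) and accept it
#' when it converges with all structural-parameter CV% at or below
#' `cv_threshold`; otherwise fall back to the one-compartment model
#' (proportional error for iohexol, additive for PAH). Amikacin profiles
#' are always described by the two-compartment model.
#'
#' @param profile A [plasma_profile()].
#' @param cv_threshold Acceptable precision bound on CV% (default 50).
#' @return A `compartmental_fit`.
#' @export
select_model <- function(profile, cv_threshold = 50) {
  arc_check(inherits(profile, "plasma_profile"), "not a plasma_profile")
  analyte <- profile$analyte
  fit2 <- tryCatch(fit_profile(profile, 2L, "proportional"),
                   error = function(e) e)
  acceptable <- function(f) {
    inherits(f, "compartmental_fit") && f$converged &&
      !any(is.na(f$cv_pct)) && all(f$cv_pct <= cv_threshold)
  }
  if (analyte == "amikacin") {
    if (inherits(fit2, "error")) {
      arc_abort(sprintf("amikacin profile %s %s: 2-compartment fit failed (%s)",
                        profile$animal_id, profile$occasion,
                        conditionMessage(fit2)), "arc_fit_error")
    }
    return(fit2)
  }
  if (acceptable(fit2)) return(fit2)
  fallback_error <- if (analyte == "pah") "additive" else "proportional"
  fit1 <- tryCatch(fit_profile(profile, 1L, fallback_error),
                   error = function(e) e)
  if (inherits(fit1, "compartmental_fit") && fit1$converged) return(fit1)
  msg2 <- if (inherits(fit2, "error")) conditionMessage(fit2) else
    sprintf("imprecise (max CV%% %.1f)", suppressWarnings(max(fit2$cv_pct)))
  msg1 <- if (inherits(fit1, "error")) conditionMessage(fit1) else
    "did not converge"
  arc_abort(sprintf(
    "profile %s %s %s: both fits failed [2-comp: %s; 1-comp: %s]",
    profile$animal_id, profile$analyte, profile$occasion, msg2, msg1),
    "arc_fit_error")
}

#' Secondary (derived) parameters of a fit
#'
#' Steady-state volume of distribution `vss = v1 + v2` (v2 = 0 for the
#' one-compartment model) and the model-based total exposure
#' `auc_inf = dose * 1e6 / (cl_tot * 60)` (ng.h/mL), the closed-form
#' integral of the fitted curve.
#'
#' @param fit A converged `compartmental_fit`.
#' @return A list with `vss` (mL/kg) and `auc_inf` (ng.h/mL).
#' @export
derived_parameters <- function(fit) {
  arc_check(inherits(fit, "compartmental_fit"), "not a compartmental_fit")
  arc_check(isTRUE(fit$converged), "fit did not converge",
            "arc_fit_error")
  list(vss = fit$vss, auc_inf = fit$auc_inf)
}
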
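# Seeded generator of complete study datasets with the statistical
# structure the analysis assumes: lognormal between-animal spread around
# the study's group-median PK parameters, multiplicative test-retest
# variability sized to the observed reproducibility, a lognormal fluid
# effect on clearance in the treatment arm, LLOQ censoring, PAH urinary
# excretion, urine output and a hematocrit/plasma-volume time course.

analyte_defaults <- function() {
  list(
    iohexol = list(dose = 64.7, cl_gm = 3.7, vss_gm = 380, lloq = 0.25,
                   residual = list(model = "proportional", sd = 0.07),
                   retest_cv = 0.058,
                   fluid_cl_mean = 1.15, fluid_cl_sd = 0.13,
                   fluid_vss_mult = 1.06),
    pah = list(dose = 10, cl_gm = 24.3, vss_gm = 490, lloq = 0.25,
               residual = list(model = "proportional", sd = 0.07),
               retest_cv = 0.18,
               fluid_cl_mean = 1.10, fluid_cl_sd = 0.13,
               fluid_vss_mult = 1.06),
    amikacin = list(dose = 7.5, cl_gm = 3.6, vss_gm = 520, lloq = 0.50,
                    residual = list(model = "proportional", sd = 0.07),
                    retest_cv = 0.055,
                    fluid_cl_mean = 1.14, fluid_cl_sd = 0.13,
                    fluid_vss_mult = 1.0))
}

#' Simulation configuration
#'
#' All knobs of the synthetic cohort generator, defaulting to the study
#' conditions: 12 + 12 animals, doses 64.7 / 10 / 7.5 mg/kg, the
#' 13-point sampling schedule (0 pre-dose, 5 min - 10 h), LLOQ censoring
#' at 0.25 / 0.25 / 0.50 ug/mL, a lognormal fluid effect on clearance
#' with mean 1.15 (iohexol) / 1.14 (amikacin) and between-animal SD 0.13,
#' test-retest dispersion sized to the reported reproducibility
#' (R ~ 5.8 / 5.5 / 18 percent), PAH fraction excreted 0.45, and urine
#' output 1.2 / 1.45 mL/kg/h at baseline with a ~2.9-fold rise under
#' fluid administration.
#'
#' @param ... Overrides for any default field. Per-analyte fields live in
#'   `analytes` (a named list of lists); `analytes_included` restricts
#'   which markers are generated.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_control = 12L, n_treatment = 12L,
    bw_mean = 14.1, bw_sd = 1.6, bw_gain_mean = 2.0, bw_gain_sd = 0.3,
    analytes = analyte_defaults(),
    analytes_included = ANALYTES,
    between_cv = 0.12, vss_between_cv = 0.12,
    v1_frac = 0.6, q_cl_ratio = 1.0, renal_cor = 0.8,
    vss_retest_cv = 0.05,
    fe_pah = 0.45,
    urine_interval_h = 2, urine_span_h = 10, urine_conc_cv = 0.05,
    uo_baseline = c(control = 1.2, treatment = 1.45),
    uo_m2_mult = c(control = 1.0, treatment = 2.9),
    uo_cv = 0.08,
    hct_mean = 30, hct_sd = 2,
    pvc_profile = list(control = c("12" = -6.70, "24" = -4.55, "36" = -1.0),
                       treatment = c("12" = 2.99, "24" = 2.53, "36" = 1.0)),
    pvc_sd = 2,
    temp_mean = 39.3, temp_sd = 0.25,
    hematology = list(leukocytes = c(16000, 2500),
                      neutrophils = c(6000, 1400),
                      lymphocytes = c(8500, 1800),
                      monocytes = c(700, 180)),
    sampling_times = c(c(5, 10, 20, 30, 45, 60) / 60,
                       c(1.5, 2, 4, 6, 8, 10)),
    include_predose = TRUE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    arc_abort(sprintf("unknown simulation_config field(s): %s",
                      paste(unknown, collapse = ", ")), "arc_config_error")
  }
  if ("analytes" %in% names(dots)) {
    for (an in names(dots$analytes)) {
      arc_check(an %in% ANALYTES, sprintf("unknown analyte '%s'", an),
                "arc_config_error")
      cfg$analytes[[an]][names(dots$analytes[[an]])] <- dots$analytes[[an]]
    }
    dots$analytes <- NULL
  }
  cfg[names(dots)] <- dots
  arc_check(cfg$n_control >= 1 && cfg$n_treatment >= 1,
            "cohort sizes must be >= 1", "arc_config_error")
  arc_check(all(cfg$analytes_included %in% ANALYTES),
            "analytes_included must be a subset of the known markers",
            "arc_config_error")
  arc_check(cfg$v1_frac > 0 && cfg$v1_frac < 1,
            "v1_frac must lie in (0, 1)", "arc_config_error")
  arc_check(cfg$fe_pah > 0 && cfg$fe_pah <= 1,
            "fe_pah must lie in (0, 1]", "arc_config_error")
  arc_check(abs(cfg$renal_cor) <= 1, "renal_cor must lie in [-1, 1]",
            "arc_config_error")
  for (an in cfg$analytes_included) {
    a <- cfg$analytes[[an]]
    arc_check(a$dose > 0 && a$cl_gm > 0 && a$vss_gm > 0 && a$lloq > 0,
              sprintf("%s: doses, parameters and LLOQ must be > 0", an),
              "arc_config_error")
  }
  structure(cfg, class = "simulation_config")
}

# lognormal deviate with arithmetic mean m and CV cv (exact moments)
rlnorm_mean <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# lognormal with arithmetic mean m and CV cv evaluated at standard-normal
# quantile z: one animal-level response deviate shared across markers
lnorm_from_z <- function(z, m, cv) {
  if (cv <= 0) return(m)
  s2 <- log(1 + cv^2)
  exp(log(m) - s2 / 2 + sqrt(s2) * z)
}

# multiplicative test-retest deviate: E[eps] = 1, dispersion sized so the
# expected duplicate CV of (x, x*eps) equals retest_cv (sd of log eps =
# retest_cv * sqrt(2))
retest_deviate <- function(retest_cv) {
  if (retest_cv <= 0) return(1)
  s <- retest_cv * sqrt(2)
  exp(stats::rnorm(1, -s^2 / 2, s))
}

# fraction of eventual urinary excretion recovered by time t for a
# biexponential plasma profile (proportional to the partial AUC)
excreted_fraction <- function(params, dose, t) {
  m <- macro_constants(params, dose)
  total <- sum(m$coefs / m$rates)
  vapply(t, function(ti) {
    1 - sum(m$coefs / m$rates * exp(-m$rates * ti)) / total
  }, numeric(1))
}

trunc_norm <- function(n, mean, sd, lower = 100) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

#' Simulate a complete study cohort
#'
#' Draws individual PK parameters (lognormal between-animal spread with a
#' shared renal latent factor across markers), applies test-retest and
#' treatment-arm fluid-effect multipliers at the second occasion,
#' generates concentration-time profiles with residual error and LLOQ
#' censoring, PAH urine collections consistent with the configured
#' fraction excreted, hematocrit series with group-specific
#' plasma-volume dynamics, and the hematology/temperature panels.
#' Deterministic given `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed.
#' @return A list of class `simulated_cohort`: `dataset` (a
#'   [study_dataset()]) and `truth` (a data frame of the generating
#'   per-animal parameters per analyte and occasion).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  arc_check(inherits(config, "simulation_config"),
            "config must be a simulation_config", "arc_config_error")
  set.seed(seed)
  n <- config$n_control + config$n_treatment
  ids <- sprintf("P%02d", seq_len(n))
  groups <- rep(c("control", "treatment"),
                c(config$n_control, config$n_treatment))
  sb_cl <- sqrt(log(1 + config$between_cv^2))
  sb_v <- sqrt(log(1 + config$vss_between_cv^2))
  rho <- config$renal_cor

  plasma <- list(); urine <- list(); animals <- list(); hct <- list()
  truth <- list()

  for (i in seq_len(n)) {
    id <- ids[i]; grp <- groups[i]
    bw1 <- stats::rnorm(1, config$bw_mean, config$bw_sd)
    bw2 <- bw1 + stats::rnorm(1, config$bw_gain_mean, config$bw_gain_sd)
    bw <- c(M1 = bw1, M2 = bw2)
    z_renal <- stats::rnorm(1)
    # one fluid-response deviate per animal, shared across markers, so
    # marker agreement persists under fluid administration
    z_fluid <- stats::rnorm(1)

    for (an in config$analytes_included) {
      a <- config$analytes[[an]]
      z_a <- stats::rnorm(1)
      eta <- rho * z_renal + sqrt(1 - rho^2) * z_a
      cl1 <- a$cl_gm * exp(sb_cl * eta)
      vss1 <- a$vss_gm * exp(sb_v * stats::rnorm(1))
      eps_cl <- retest_deviate(a$retest_cv)
      eps_v <- retest_deviate(config$vss_retest_cv)
      fl_cl <- if (grp == "treatment") {
        lnorm_from_z(z_fluid, a$fluid_cl_mean,
                     if (a$fluid_cl_mean > 0) a$fluid_cl_sd / a$fluid_cl_mean
                     else 0)
      } else 1
      fl_v <- if (grp == "treatment") a$fluid_vss_mult else 1
      cl <- c(M1 = cl1, M2 = cl1 * eps_cl * fl_cl)
      vss <- c(M1 = vss1, M2 = vss1 * eps_v * fl_v)

      for (occ in OCCASIONS) {
        v1 <- config$v1_frac * vss[occ]
        par <- pk_parameters(cl[occ], v1, config$q_cl_ratio * cl[occ],
                             vss[occ] - v1)
        f <- predict_concentration(par, a$dose, config$sampling_times)
        obs <- if (a$residual$model == "proportional") {
          f * (1 + stats::rnorm(length(f), 0, a$residual$sd))
        } else {
          f + stats::rnorm(length(f), 0, a$residual$sd)
        }
        blq <- obs < a$lloq
        tt <- config$sampling_times
        cc <- ifelse(blq, NA_real_, obs)
        if (config$include_predose) {
          tt <- c(0, tt); cc <- c(NA_real_, cc); blq <- c(FALSE, blq)
        }
        plasma[[length(plasma) + 1]] <- data.frame(
          animal_id = id, group = grp, occasion = occ, analyte = an,
          dose_mg_per_kg = a$dose, body_weight_kg = unname(bw[occ]),
          time_h = tt, conc_ug_per_ml = cc, blq = as.integer(blq),
          lloq_ug_per_ml = a$lloq)
        truth[[length(truth) + 1]] <- data.frame(
          animal_id = id, group = grp, occasion = occ, analyte = an,
          cl_tot = unname(cl[occ]), vss = unname(vss[occ]),
          body_weight_kg = unname(bw[occ]))

        if (an == "pah") {
          starts <- seq(0, config$urine_span_h - config$urine_interval_h,
                        by = config$urine_interval_h)
          ends <- starts + config$urine_interval_h
          rate <- config$uo_baseline[[grp]] *
            (if (occ == "M2") config$uo_m2_mult[[grp]] else 1) *
            rlnorm_mean(1, 1, config$uo_cv)
          vols <- rate * bw[occ] * (ends - starts)
          fr <- excreted_fraction(par, a$dose, c(starts, ends))
          amt_mg <- config$fe_pah * a$dose * bw[occ] *
            (fr[seq_along(ends) + length(starts)] - fr[seq_along(starts)])
          conc <- amt_mg * 1000 / vols *
            rlnorm_mean(length(vols), 1, config$urine_conc_cv)
          urine[[length(urine) + 1]] <- data.frame(
            animal_id = id, occasion = occ, start_h = starts, end_h = ends,
            volume_ml = vols, conc_ug_per_ml = conc, leaked = 0L)
        }
      }
    }

    hem <- config$hematology
    for (occ in OCCASIONS) {
      animals[[length(animals) + 1]] <- data.frame(
        animal_id = id, group = grp, occasion = occ,
        body_weight_kg = unname(bw[occ]),
        temp_c = stats::rnorm(1, config$temp_mean, config$temp_sd),
        leukocytes_per_ul = trunc_norm(1, hem$leukocytes[1],
                                       hem$leukocytes[2]),
        neutrophils_per_ul = trunc_norm(1, hem$neutrophils[1],
                                        hem$neutrophils[2]),
        lymphocytes_per_ul = trunc_norm(1, hem$lymphocytes[1],
                                        hem$lymphocytes[2]),
        monocytes_per_ul = trunc_norm(1, hem$monocytes[1],
                                      hem$monocytes[2], 50))
    }

    h1 <- min(max(stats::rnorm(1, config$hct_mean, config$hct_sd), 15), 55)
    hct[[length(hct) + 1]] <- data.frame(
      animal_id = id, time_since_fluid_start_h = 0, hct_pct = h1)
    prof <- config$pvc_profile[[grp]]
    for (tm in names(prof)) {
      pvc <- prof[[tm]] + stats::rnorm(1, 0, config$pvc_sd)
      h2 <- h1 / (1 + pvc * (100 - h1) / 1e4)
      hct[[length(hct) + 1]] <- data.frame(
        animal_id = id, time_since_fluid_start_h = as.numeric(tm),
        hct_pct = min(max(h2, 10), 70))
    }
  }

  dataset <- study_dataset(
    plasma = do.call(rbind, plasma),
    urine = if (length(urine)) do.call(rbind, urine) else NULL,
    animals = do.call(rbind, animals),
    hematocrit = do.call(rbind, hct))
  structure(list(dataset = dataset,
                 truth = do.call(rbind, truth),
                 config = config, seed = seed),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> seed %d, %d control + %d treatment animals, analytes: %s\n",
              x$seed, x$config$n_control, x$config$n_treatment,
              paste(x$config$analytes_included, collapse = ", ")))
  print(x$dataset)
  invisible(x)
}

#' Inject controlled anomalies into a dataset
#'
#' Exercises the screening filters: `leukocytosis` gives one animal the
#' study's exclusion signature at the second occasion (leukocytes
#' 32,690/uL, neutrophils 23,341/uL, body temperature +1.2 degC over
#' baseline); `urine_leak` marks chosen urine intervals as leaked.
#'
#' @param dataset A [study_dataset()].
#' @param anomalies Named list. `leukocytosis`: an animal id.
#'   `urine_leak`: a list (or list of lists) with `animal_id`,
#'   `occasion`, and optional `interval` (index in start-time order,
#'   default 1).
#' @return The modified, re-validated dataset.
#' @export
inject_anomalies <- function(dataset, anomalies = list()) {
  validate_study_dataset(dataset)
  if (length(anomalies) == 0) return(dataset)
  unknown <- setdiff(names(anomalies), c("leukocytosis", "urine_leak"))
  if (length(unknown) > 0) {
    arc_abort(sprintf("unknown anomaly key(s): %s",
                      paste(unknown, collapse = ", ")), "arc_config_error")
  }
  if (!is.null(anomalies$leukocytosis)) {
    id <- anomalies$leukocytosis
    a <- dataset$animals
    arc_check(id %in% a$animal_id,
              sprintf("animal '%s' not in dataset", id), "arc_config_error")
    i1 <- which(a$animal_id == id & a$occasion == "M1")
    i2 <- which(a$animal_id == id & a$occasion == "M2")
    arc_check(length(i1) == 1 && length(i2) == 1,
              "leukocytosis anomaly needs both occasions", "arc_config_error")
    a$leukocytes_per_ul[i2] <- 32690
    a$neutrophils_per_ul[i2] <- 23341
    a$temp_c[i2] <- a$temp_c[i1] + 1.2
    dataset$animals <- a
  }
  if (!is.null(anomalies$urine_leak)) {
    leaks <- anomalies$urine_leak
    if (!is.null(leaks$animal_id)) leaks <- list(leaks)
    u <- dataset$urine
    for (lk in leaks) {
      rows <- which(u$animal_id == lk$animal_id &
                    u$occasion == lk$occasion)
      arc_check(length(rows) > 0,
                sprintf("no urine intervals for %s %s", lk$animal_id,
                        lk$occasion), "arc_config_error")
      rows <- rows[order(u$start_h[rows])]
      k <- lk$interval %||% 1L
      arc_check(k >= 1 && k <= length(rows),
                "urine_leak interval index out of range", "arc_config_error")
      u$leaked[rows[k]] <- 1L
    }
    dataset$urine <- u
  }
  validate_study_dataset(dataset)
  dataset
}
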
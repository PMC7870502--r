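# End-to-end orchestration: screen -> fit -> derive -> compare -> report.
# Mirrors the study's analysis battery: within-group one-sided signed-rank
# tests on clearance, between-group one-sided rank-sum tests on clearance
# change, two-sided tests for V_ss / AUC / urine output, per-timepoint
# plasma-volume comparisons, reproducibility and Bland-Altman agreement.

#' Analysis configuration
#'
#' @param cv_threshold Precision bound (CV%) for accepting the
#'   two-compartment fit, see [select_model()].
#' @param alpha Significance level (reported, not used for filtering).
#' @param delta_t_threshold Temperature-rise threshold (degC) of the
#'   infection screen.
#' @param ref_ranges Hematology upper reference bounds.
#' @param extrap_limit Extrapolated-AUC gate (%), see
#'   [check_extrapolation()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cv_threshold = 50, alpha = 0.05,
                            delta_t_threshold = 1.0,
                            ref_ranges = default_ref_ranges(),
                            extrap_limit = 10) {
  structure(list(cv_threshold = cv_threshold, alpha = alpha,
                 delta_t_threshold = delta_t_threshold,
                 ref_ranges = ref_ranges, extrap_limit = extrap_limit),
            class = "analysis_config")
}

fit_row <- function(fit, nca, extrap_limit) {
  p <- fit$params
  data.frame(
    animal_id = fit$animal_id, group = fit$group, analyte = fit$analyte,
    occasion = fit$occasion, n_compartments = p$n_compartments,
    error_model = fit$error_model, cl_tot = p$cl_tot, v1 = p$v1,
    q = p$q %||% NA_real_, v2 = p$v2 %||% NA_real_, vss = fit$vss,
    auc_inf = fit$auc_inf, sigma = fit$sigma,
    max_cv_pct = if (any(is.na(fit$cv_pct))) NA_real_ else max(fit$cv_pct),
    converged = fit$converged, n_obs = fit$n_obs,
    auc_inf_nca = if (is.null(nca)) NA_real_ else nca$auc_inf_nca,
    lambda_z = if (is.null(nca)) NA_real_ else nca$lambda_z,
    extrap_pct = if (is.null(nca)) NA_real_ else nca$extrap_pct,
    extrap_ok = if (is.null(nca)) NA else
      check_extrapolation(nca, extrap_limit))
}

# paired M1/M2 wide table of one fitted parameter
paired_param <- function(fits, analyte, param) {
  f <- fits[fits$analyte == analyte, ]
  m1 <- f[f$occasion == "M1", c("animal_id", "group", param)]
  m2 <- f[f$occasion == "M2", c("animal_id", param)]
  names(m1)[3] <- "m1"; names(m2)[2] <- "m2"
  merge(m1, m2, by = "animal_id")
}

safe_test <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

#' Run the full study analysis
#'
#' Applies the screening filters (infection screen over hematology and
#' temperature; urine-leak completeness for renal clearance), fits every
#' profile with [select_model()] plus the [nca_auc()] extrapolation gate,
#' derives renal clearance, urine output and plasma-volume changes, runs
#' the study's hypothesis-test battery, and assembles Table-1/Table-2
#' style summaries, reproducibility, agreement results and an exclusion
#' log.
#'
#' @param dataset A validated [study_dataset()] (or `simulated_cohort`,
#'   whose `$dataset` is used).
#' @param config An [analysis_config()].
#' @return An object of class `arc_report`; a list of data frames:
#'   `fits`, `summary`, `reproducibility`, `agreement`, `correlations`,
#'   `tests`, `renal`, `urine_output`, `pvc`, `hct_trend`, `exclusions`,
#'   `errors`, plus `included` (animal ids) and `n_by_group`.
#' @export
run_analysis <- function(dataset, config = analysis_config()) {
  if (inherits(dataset, "simulated_cohort")) dataset <- dataset$dataset
  validate_study_dataset(dataset)

  all_ids <- unique(c(dataset$plasma$animal_id, dataset$animals$animal_id))
  group_of <- function(ids) {
    map <- unique(rbind(dataset$plasma[, c("animal_id", "group")],
                        dataset$animals[, c("animal_id", "group")]))
    map$group[match(ids, map$animal_id)]
  }

  # -- screening ------------------------------------------------------
  exclusions <- data.frame(animal_id = character(0), group = character(0),
                           stage = character(0), scope = character(0),
                           reason = character(0))
  if (nrow(dataset$animals) > 0) {
    for (id in unique(dataset$animals$animal_id)) {
      rows <- dataset$animals[dataset$animals$animal_id == id, ]
      if (!all(OCCASIONS %in% rows$occasion)) next
      scr <- tryCatch(
        infection_screen(rows, config$ref_ranges, config$delta_t_threshold),
        error = function(e) list(decision = "include", reason = NA))
      if (scr$decision == "exclude") {
        exclusions <- rbind(exclusions, data.frame(
          animal_id = id, group = rows$group[1],
          stage = "infection_screen", scope = "study",
          reason = scr$reason))
      }
    }
  }
  included <- setdiff(all_ids, exclusions$animal_id)

  # urine completeness (renal-clearance scope only)
  renal_eligible <- character(0)
  if (nrow(dataset$urine) > 0) {
    for (id in intersect(unique(dataset$urine$animal_id), included)) {
      u <- dataset$urine[dataset$urine$animal_id == id, ]
      flt <- urine_completeness_filter(u)
      if (flt$eligible) {
        renal_eligible <- c(renal_eligible, id)
      } else {
        exclusions <- rbind(exclusions, data.frame(
          animal_id = id, group = group_of(id), stage = "urine_filter",
          scope = "renal_clearance", reason = flt$reason))
      }
    }
  }

  # -- compartmental fits ---------------------------------------------
  profs <- profiles(dataset)
  profs <- profs[vapply(profs, function(p) p$animal_id %in% included,
                        logical(1))]
  fit_rows <- list(); fit_objs <- list()
  errors <- data.frame(animal_id = character(0), analyte = character(0),
                       occasion = character(0), message = character(0))
  for (pr in profs) {
    fit <- tryCatch(select_model(pr, config$cv_threshold),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      errors <- rbind(errors, data.frame(
        animal_id = pr$animal_id, analyte = pr$analyte,
        occasion = pr$occasion, message = conditionMessage(fit)))
      next
    }
    nca <- tryCatch(nca_auc(pr), error = function(e) NULL)
    fit_rows[[length(fit_rows) + 1]] <- fit_row(fit, nca,
                                                config$extrap_limit)
    fit_objs[[length(fit_objs) + 1]] <- fit
  }
  fits <- if (length(fit_rows)) do.call(rbind, fit_rows) else
    data.frame()
  rownames(fits) <- NULL

  # -- renal clearance and urine output -------------------------------
  renal <- data.frame(); uo <- data.frame()
  if (nrow(dataset$urine) > 0 && nrow(fits) > 0) {
    rrows <- list(); urows <- list()
    for (id in intersect(unique(dataset$urine$animal_id), included)) {
      for (occ in OCCASIONS) {
        u <- dataset$urine[dataset$urine$animal_id == id &
                           dataset$urine$occasion == occ, ]
        if (nrow(u) == 0) next
        frow <- fits[fits$animal_id == id & fits$analyte == "pah" &
                     fits$occasion == occ, ]
        bw <- dataset$plasma$body_weight_kg[
          dataset$plasma$animal_id == id &
          dataset$plasma$occasion == occ][1]
        if (is.na(bw)) next
        exc <- cumulative_excretion(u, bw)
        if (id %in% renal_eligible && nrow(frow) == 1) {
          rrows[[length(rrows) + 1]] <- data.frame(
            animal_id = id, group = group_of(id), occasion = occ,
            ae_mg_per_kg = exc$ae,
            cl_r_ml_min_kg = renal_clearance(exc$ae, frow$auc_inf),
            complete = exc$complete)
        }
        if (exc$complete) {
          urows[[length(urows) + 1]] <- data.frame(
            animal_id = id, group = group_of(id), occasion = occ,
            uo_ml_kg_h = urine_output_rate(u, bw))
        }
      }
    }
    if (length(rrows)) renal <- do.call(rbind, rrows)
    if (length(urows)) uo <- do.call(rbind, urows)
  }

  # -- plasma volume change -------------------------------------------
  pvc <- data.frame()
  if (nrow(dataset$hematocrit) > 0) {
    prow <- list()
    for (id in intersect(unique(dataset$hematocrit$animal_id), included)) {
      h <- dataset$hematocrit[dataset$hematocrit$animal_id == id, ]
      h <- h[order(h$time_since_fluid_start_h), ]
      base <- h$hct_pct[h$time_since_fluid_start_h == 0]
      if (length(base) != 1) next
      later <- h[h$time_since_fluid_start_h > 0, ]
      if (nrow(later) == 0) next
      prow[[length(prow) + 1]] <- data.frame(
        animal_id = id, group = group_of(id),
        time_h = later$time_since_fluid_start_h,
        pct_change = plasma_volume_change(base, later$hct_pct))
    }
    if (length(prow)) pvc <- do.call(rbind, prow)
  }

  # -- summaries ------------------------------------------------------
  summary_tab <- data.frame()
  analytes_present <- unique(fits$analyte)
  for (an in analytes_present) {
    f <- fits[fits$analyte == an, ]
    for (param in c("cl_tot", "vss", "auc_inf")) {
      summary_tab <- rbind(summary_tab, cbind(
        analyte = an,
        summarize_group(f[[param]], f$group, f$occasion, param)))
    }
  }
  if (nrow(renal) > 0) {
    summary_tab <- rbind(summary_tab, cbind(
      analyte = "pah",
      summarize_group(renal$cl_r_ml_min_kg, renal$group, renal$occasion,
                      "cl_r")))
  }
  if (nrow(uo) > 0) {
    # restricted, as in the study, to animals with two complete collections
    both <- names(which(table(uo$animal_id) == 2))
    uob <- uo[uo$animal_id %in% both, ]
    if (nrow(uob) > 0) {
      summary_tab <- rbind(summary_tab, cbind(
        analyte = "urine",
        summarize_group(uob$uo_ml_kg_h, uob$group, uob$occasion,
                        "urine_output")))
    }
  }

  # -- reproducibility (control group, Table 2 mirror) ----------------
  repro <- data.frame(); repro_cvs <- list()
  for (an in analytes_present) {
    w <- paired_param(fits, an, "cl_tot")
    w <- w[w$group == "control", ]
    if (nrow(w) < 1) next
    cvs <- duplicate_cv(w$m1, w$m2)
    rs <- reproducibility(cvs)
    repro <- rbind(repro, data.frame(
      analyte = an, n = rs$n, mean_cv_pct = rs$mean_cv,
      cv_min_pct = min(cvs), cv_max_pct = max(cvs), r_pct = rs$r_pct))
    repro_cvs[[an]] <- cvs
  }

  # -- agreement and correlations -------------------------------------
  agreement <- data.frame(); correlations <- data.frame()
  add_ba <- function(tag, a, b) {
    ba <- safe_test(bland_altman(a, b, "percent"))
    if (is.null(ba)) return()
    agreement <<- rbind(agreement, data.frame(
      comparison = tag, n = ba$n, bias_pct = ba$bias,
      loa_lower_pct = ba$loa_lower, loa_upper_pct = ba$loa_upper))
  }
  for (an in analytes_present) {
    w <- paired_param(fits, an, "cl_tot")
    w <- w[w$group == "control", ]
    if (nrow(w) >= 2) add_ba(sprintf("%s_cl_M1_vs_M2_control", an),
                             w$m1, w$m2)
  }
  if (all(c("iohexol", "amikacin") %in% analytes_present)) {
    io <- fits[fits$analyte == "iohexol", ]
    am <- fits[fits$analyte == "amikacin", ]
    for (occ_tag in list(c("M1", "baseline"), c("M2", "fluid"))) {
      occ <- occ_tag[1]
      iw <- io[io$occasion == occ, c("animal_id", "group", "cl_tot")]
      aw <- am[am$occasion == occ, c("animal_id", "cl_tot")]
      if (occ == "M2") iw <- iw[iw$group == "treatment", ]
      m <- merge(iw, aw, by = "animal_id",
                 suffixes = c("_ioh", "_ami"))
      if (nrow(m) >= 3) {
        # marker-agreement convention: (CL_IOH - CL_AMI) / pair mean
        add_ba(sprintf("iohexol_vs_amikacin_%s", occ_tag[2]),
               m$cl_tot_ami, m$cl_tot_ioh)
        pr <- safe_test(pearson_r(m$cl_tot_ioh, m$cl_tot_ami))
        if (!is.null(pr)) {
          correlations <- rbind(correlations, data.frame(
            comparison = sprintf("iohexol_vs_amikacin_%s", occ_tag[2]),
            r = pr$r, p_value = pr$p_value, n = pr$n))
        }
      }
    }
  }

  # -- hypothesis tests -----------------------------------------------
  tests <- data.frame()
  add_test <- function(parameter, analyte, comparison, tr) {
    if (is.null(tr)) return()
    tests <<- rbind(tests, data.frame(
      parameter = parameter, analyte = analyte, comparison = comparison,
      alternative = tr$alternative, method = tr$method,
      statistic = tr$statistic, p_value = tr$p_value,
      n = tr$n, m = tr$m %||% NA_integer_))
  }
  paired_battery <- function(w, parameter, analyte, sided_within,
                             sided_between) {
    for (grp in GROUPS) {
      d <- w$m2[w$group == grp] - w$m1[w$group == grp]
      if (length(d) < 1) next
      add_test(parameter, analyte, sprintf("within_%s_M2_vs_M1", grp),
               safe_test(wilcoxon_signed_rank(d, sided_within)))
    }
    chg <- 100 * (w$m2 - w$m1) / w$m1
    tr_chg <- chg[w$group == "treatment"]
    ct_chg <- chg[w$group == "control"]
    if (length(tr_chg) >= 1 && length(ct_chg) >= 1) {
      add_test(parameter, analyte, "between_change_treatment_vs_control",
               safe_test(mann_whitney_u(tr_chg, ct_chg, sided_between)))
    }
  }
  for (an in analytes_present) {
    paired_battery(paired_param(fits, an, "cl_tot"), "cl_tot", an,
                   "greater", "greater")
    paired_battery(paired_param(fits, an, "vss"), "vss", an,
                   "two.sided", "two.sided")
    paired_battery(paired_param(fits, an, "auc_inf"), "auc_inf", an,
                   "two.sided", "two.sided")
  }
  paired_from <- function(df, valuecol) {
    m1 <- df[df$occasion == "M1", c("animal_id", "group", valuecol)]
    m2 <- df[df$occasion == "M2", c("animal_id", valuecol)]
    names(m1)[3] <- "m1"; names(m2)[2] <- "m2"
    merge(m1, m2, by = "animal_id")
  }
  if (nrow(renal) > 0) {
    w <- paired_from(renal, "cl_r_ml_min_kg")
    if (nrow(w) > 0) paired_battery(w, "cl_r", "pah", "greater", "greater")
  }
  if (nrow(uo) > 0) {
    w <- paired_from(uo, "uo_ml_kg_h")
    if (nrow(w) > 0) {
      paired_battery(w, "urine_output", "urine", "two.sided", "two.sided")
    }
  }
  if (nrow(pvc) > 0) {
    for (tm in sort(unique(pvc$time_h))) {
      x <- pvc$pct_change[pvc$time_h == tm & pvc$group == "treatment"]
      y <- pvc$pct_change[pvc$time_h == tm & pvc$group == "control"]
      if (length(x) >= 1 && length(y) >= 1) {
        add_test("pvc_pct", "hematocrit",
                 sprintf("between_groups_at_%gh", tm),
                 safe_test(mann_whitney_u(x, y, "two.sided")))
      }
    }
  }

  # hematocrit linear trend per group
  hct_trend <- data.frame()
  if (nrow(dataset$hematocrit) > 0 && nrow(dataset$animals) > 0) {
    h <- dataset$hematocrit[dataset$hematocrit$animal_id %in% included, ]
    h$group <- group_of(h$animal_id)
    for (grp in intersect(GROUPS, unique(h$group))) {
      hg <- h[h$group == grp, ]
      lt <- safe_test(linear_trend_test(hg$time_since_fluid_start_h,
                                        hg$hct_pct))
      if (!is.null(lt)) {
        hct_trend <- rbind(hct_trend, data.frame(
          group = grp, slope = lt$slope, p_value = lt$p_value, n = lt$n))
      }
    }
  }

  grp_incl <- group_of(included)
  structure(
    list(fits = fits, summary = summary_tab, reproducibility = repro,
         repro_cvs = repro_cvs, agreement = agreement,
         correlations = correlations, tests = tests, renal = renal,
         urine_output = uo, pvc = pvc, hct_trend = hct_trend,
         exclusions = exclusions, errors = errors,
         included = included,
         n_by_group = table(factor(grp_incl, levels = GROUPS)),
         config = config),
    class = "arc_report")
}

#' @export
print.arc_report <- function(x, ...) {
  cat(sprintf("<arc_report> %d fitted profiles, %d included animals (control %d, treatment %d)\n",
              nrow(x$fits), length(x$included),
              x$n_by_group[["control"]], x$n_by_group[["treatment"]]))
  if (nrow(x$exclusions) > 0) {
    cat("exclusions:\n")
    print(x$exclusions, row.names = FALSE)
  }
  if (nrow(x$reproducibility) > 0) {
    cat("reproducibility (control group):\n")
    print(x$reproducibility, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes each report table as CSV plus a JSON manifest (file list,
#' group sizes, significance level).
#'
#' @param report An [run_analysis()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  arc_check(inherits(report, "arc_report"), "not an arc_report")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("fits", "summary", "reproducibility", "agreement",
              "correlations", "tests", "renal", "urine_output", "pvc",
              "hct_trend", "exclusions", "errors")
  files <- character(0)
  for (tb in tables) {
    df <- report[[tb]]
    if (!is.data.frame(df)) next
    path <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <- c(files, basename(path))
  }
  manifest <- list(
    files = files,
    n_included = length(report$included),
    n_by_group = as.list(report$n_by_group),
    alpha = report$config$alpha)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
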
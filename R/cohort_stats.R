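# Nonparametric group comparisons (exact where the sample permits),
# hematocrit trend test, screening filters and Table-1-style summaries.
#
# Exact p-values come from the exact null distributions in stats::
# wilcox.test (signed-rank / rank-sum); the approximate branch uses the
# tie-corrected normal approximation with continuity correction.

test_result <- function(statistic, p_value, alternative, method, n, m = NULL) {
  structure(list(statistic = unname(statistic), p_value = p_value,
                 alternative = alternative, method = method, n = n, m = m),
            class = "arc_test_result")
}

#' @export
print.arc_test_result <- function(x, ...) {
  cat(sprintf("<test> statistic %.4g, p = %.4g (%s, %s, n = %d%s)\n",
              x$statistic, x$p_value, x$alternative, x$method, x$n,
              if (is.null(x$m)) "" else sprintf(", m = %d", x$m)))
  invisible(x)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (Wilcoxon's convention). The exact null
#' distribution is used when n <= `exact_max` after zero removal and the
#' absolute differences are untied; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param d Paired differences.
#' @param alternative `"greater"` (positive shift), `"less"`, or
#'   `"two.sided"`.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return An `arc_test_result` with the V statistic.
#' @export
wilcoxon_signed_rank <- function(d,
                                 alternative = c("greater", "less",
                                                 "two.sided"),
                                 exact_max = 12L) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  if (length(d) == 0) {
    arc_abort("all paired differences are zero",
              "arc_degenerate_input_error")
  }
  exact <- length(d) <= exact_max && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = TRUE))
  test_result(wt$statistic, wt$p.value, alternative,
              if (exact) "exact" else "approximate", length(d))
}

#' Mann-Whitney U test (two independent samples)
#'
#' Tests a location shift of `x` relative to `y`; `alternative =
#' "greater"` means `x` tends to exceed `y`. Exact enumeration over
#' arrangements is used when `n + m <= exact_max` and there are no ties
#' across the pooled sample; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y The two samples.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @param exact_max Largest pooled size for which the exact distribution
#'   is used.
#' @return An `arc_test_result` with the U statistic of `x`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("greater", "less", "two.sided"),
                           exact_max = 14L) {
  alternative <- match.arg(alternative)
  arc_check(length(x) >= 1 && length(y) >= 1,
            "both samples must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    # fully tied pooled sample: no evidence against the null
    return(test_result(length(x) * length(y) / 2, 1, alternative,
                       "approximate", length(x), length(y)))
  }
  exact <- (length(x) + length(y)) <= exact_max &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  test_result(wt$statistic, wt$p.value, alternative,
              if (exact) "exact" else "approximate",
              length(x), length(y))
}

#' Linear trend test
#'
#' Ordinary least-squares regression of a series on time with a
#' two-sided t-test on the slope, as used for the hematocrit-over-time
#' evaluation.
#'
#' @param time Time points (at least 3 distinct values).
#' @param value Observed values.
#' @return A list with `slope`, `intercept`, `p_value`, `n`.
#' @export
linear_trend_test <- function(time, value) {
  arc_check(length(time) == length(value), "time/value length mismatch")
  arc_check(length(unique(time)) >= 3,
            "need at least 3 distinct time points")
  fit <- stats::lm(value ~ time)
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) < 2 || is.na(sm[2, 4])) 1 else sm[2, 4]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = p, n = length(time))
}

#' Default hematology reference ranges
#'
#' Upper reference bounds (cells/uL) used by the infection screen,
#' matching the clinical reference intervals applied in the study.
#'
#' @return Named list of upper bounds.
#' @export
default_ref_ranges <- function() {
  list(leukocytes_upper = 22800, neutrophils_upper = 9600)
}

#' Infection/inflammation screening filter
#'
#' Excludes an animal when an extreme hematology deviation (leukocyte or
#' neutrophil count above its upper reference bound at either occasion)
#' coincides with a rise in body temperature of at least
#' `delta_t_threshold` between the two occasions. An isolated hematology
#' outlier without fever, or fever alone, does not exclude.
#'
#' @param animal_rows The animal's rows of the animals table (one per
#'   occasion, M1 and M2).
#' @param ref_ranges Named list of upper bounds, see
#'   [default_ref_ranges()].
#' @param delta_t_threshold Temperature rise threshold (degrees C).
#' @return A list with `decision` (`"include"`/`"exclude"`) and `reason`.
#' @export
infection_screen <- function(animal_rows,
                             ref_ranges = default_ref_ranges(),
                             delta_t_threshold = 1.0) {
  need <- c("occasion", "temp_c", "leukocytes_per_ul", "neutrophils_per_ul")
  check_columns(animal_rows, need, "animal record")
  m1 <- animal_rows[animal_rows$occasion == "M1", ]
  m2 <- animal_rows[animal_rows$occasion == "M2", ]
  if (nrow(m1) != 1 || nrow(m2) != 1 ||
      anyNA(m1[, need[-1]]) || anyNA(m2[, need[-1]])) {
    arc_abort("hematology and temperature required for both occasions",
              "arc_missing_data_error")
  }
  high <- function(col, upper) {
    max(m1[[col]], m2[[col]]) > upper
  }
  hema_flag <- high("leukocytes_per_ul", ref_ranges$leukocytes_upper) ||
    high("neutrophils_per_ul", ref_ranges$neutrophils_upper)
  dt <- m2$temp_c - m1$temp_c
  if (hema_flag && dt >= delta_t_threshold) {
    list(decision = "exclude",
         reason = sprintf(
           "hematology above reference with temperature rise of %.1f degC",
           dt))
  } else {
    list(decision = "include", reason = "no combined hematology/fever signal")
  }
}

#' Urine-collection completeness filter for renal clearance
#'
#' An animal is eligible for renal-clearance calculation only when both
#' occasions have a complete (leak-free, non-empty) urine collection; a
#' leak during either measurement excludes the animal from renal
#' clearance entirely.
#'
#' @param urine Urine intervals for one animal (column `occasion`,
#'   `leaked`).
#' @return A list with `eligible` (logical) and `reason`.
#' @export
urine_completeness_filter <- function(urine) {
  for (occ in OCCASIONS) {
    rows <- urine[urine$occasion == occ, , drop = FALSE]
    if (nrow(rows) == 0) {
      return(list(eligible = FALSE,
                  reason = sprintf("no urine collection at %s", occ)))
    }
    if (any(rows$leaked == 1)) {
      return(list(eligible = FALSE,
                  reason = sprintf("urine leakage at %s", occ)))
    }
  }
  list(eligible = TRUE, reason = "complete collections at both occasions")
}

#' Median and quartile summaries per group cell
#'
#' Median (25th-75th percentile) per group x occasion cell, the study's
#' reporting convention, using linearly interpolated quantiles.
#'
#' @param values Numeric values.
#' @param group,occasion Cell labels, recycled against `values`.
#' @param parameter Parameter name carried into the output.
#' @return A data frame with one row per non-empty cell: `parameter`,
#'   `group`, `occasion`, `n`, `p25`, `median`, `p75`.
#' @export
summarize_group <- function(values, group, occasion, parameter = "value") {
  df <- data.frame(values = values, group = group, occasion = occasion)
  df <- df[!is.na(df$values), , drop = FALSE]
  if (nrow(df) == 0) {
    warning("no non-missing values to summarize")
    return(data.frame(parameter = character(0), group = character(0),
                      occasion = character(0), n = integer(0),
                      p25 = numeric(0), median = numeric(0),
                      p75 = numeric(0)))
  }
  out <- do.call(rbind, lapply(
    split(df, interaction(df$group, df$occasion, drop = TRUE)),
    function(cell) {
      q <- stats::quantile(cell$values, c(0.25, 0.5, 0.75), type = 7,
                           names = FALSE)
      data.frame(parameter = parameter, group = cell$group[1],
                 occasion = cell$occasion[1], n = nrow(cell),
                 p25 = q[1], median = q[2], p75 = q[3])
    }))
  rownames(out) <- NULL
  out
}
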
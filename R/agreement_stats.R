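# Test-retest reproducibility and between-marker agreement statistics:
# duplicate coefficients of variation, the quadratic-mean reproducibility
# R, Bland-Altman bias and 95% limits of agreement, and the Pearson
# correlation.

#' Coefficient of variation of a duplicate determination
#'
#' `100 * sd(x1, x2) / mean(x1, x2)` with the two-point SD
#' `|x1 - x2| / sqrt(2)`.
#'
#' @param x1,x2 The duplicate measurements, both > 0. Vectorized.
#' @return CV in percent.
#' @export
duplicate_cv <- function(x1, x2) {
  arc_check(all(x1 > 0) && all(x2 > 0),
            "duplicate measurements must be > 0")
  100 * (abs(x1 - x2) / sqrt(2)) / ((x1 + x2) / 2)
}

#' Reproducibility of duplicate measurements
#'
#' Quadratic-mean coefficient of variation
#' \eqn{R = \sqrt{\sum_i CV_i^2 / n}} over `n` subjects with duplicate
#' determinations. By the power-mean inequality `R >=` the arithmetic
#' mean CV, with equality iff all CVs are equal.
#'
#' @param cvs Per-subject duplicate CVs (percent), non-negative.
#' @return A list of class `reproducibility_summary`: `n`, `cvs`,
#'   `mean_cv`, `r_pct`.
#' @export
reproducibility <- function(cvs) {
  arc_check(length(cvs) >= 1, "need at least one CV")
  arc_check(all(cvs >= 0), "CVs must be >= 0")
  structure(
    list(n = length(cvs), cvs = cvs, mean_cv = mean(cvs),
         r_pct = sqrt(mean(cvs^2))),
    class = "reproducibility_summary")
}

#' Bland-Altman agreement analysis
#'
#' Percent mode (the study's figure convention): per-pair difference
#' `100 * (b - a) / mean(a, b)`; absolute mode: `b - a`. Bias is the mean
#' difference; 95% limits of agreement are `bias +/- 1.96 * sd` with the
#' n-1 denominator.
#'
#' @param a,b Paired measurements (e.g. measurement 1 and measurement 2,
#'   or two markers), equal length, n >= 2.
#' @param mode `"percent"` or `"absolute"`.
#' @return A list of class `agreement_result`: `bias`, `loa_lower`,
#'   `loa_upper`, `per_pair_diffs`, `n`, `mode`.
#' @export
bland_altman <- function(a, b, mode = c("percent", "absolute")) {
  mode <- match.arg(mode)
  arc_check(length(a) == length(b), "a and b must have equal length")
  if (length(a) < 2) {
    arc_abort("Bland-Altman requires at least 2 pairs",
              "arc_insufficient_data_error")
  }
  if (mode == "percent") {
    m <- (a + b) / 2
    arc_check(all(m > 0), "pair means must be > 0 in percent mode")
    diffs <- 100 * (b - a) / m
  } else {
    diffs <- b - a
  }
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  structure(
    list(bias = bias, loa_lower = bias - 1.96 * s,
         loa_upper = bias + 1.96 * s, per_pair_diffs = diffs,
         n = length(diffs), mode = mode),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else ""
  cat(sprintf("<agreement_result> n = %d, bias %.2f%s, 95%% LoA (%.2f, %.2f)%s\n",
              x$n, x$bias, unit, x$loa_lower, x$loa_upper, unit))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the t-distribution test on n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors, n >= 3, each with nonzero variance.
#' @return A list with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  arc_check(length(x) == length(y) && length(x) >= 3,
            "need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    arc_abort("zero variance in one of the inputs",
              "arc_degenerate_input_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
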
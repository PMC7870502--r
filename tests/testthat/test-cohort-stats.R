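test_that("signed-rank worked examples match exhaustive enumeration", {
  t1 <- wilcoxon_signed_rank(c(1, 2, 3), "greater")
  expect_equal(t1$p_value, 1 / 8)
  expect_identical(t1$method, "exact")

  t2 <- wilcoxon_signed_rank(c(-1, -2, -3), "greater")
  expect_equal(t2$p_value, 1)

  expect_error(wilcoxon_signed_rank(c(0, 0)),
               class = "arc_degenerate_input_error")
})

test_that("exact signed-rank p equals brute-force enumeration, n <= 8", {
  set.seed(31)
  for (n in 3:8) {
    for (rep in 1:3) {
      d <- round(rnorm(n, 0.3, 1), 6)
      d <- d[d != 0]
      if (length(d) < 2 || anyDuplicated(abs(d))) next
      for (alt in c("greater", "less", "two.sided")) {
        got <- wilcoxon_signed_rank(d, alt)
        expect_identical(got$method, "exact")
        expect_equal(got$p_value, signed_rank_enum_p(d, alt),
                     tolerance = 1e-12,
                     label = sprintf("signed rank n=%d alt=%s", n, alt))
      }
    }
  }
})

test_that("Mann-Whitney worked examples match enumeration", {
  # y tends greater <=> x shifted "less"
  t1 <- mann_whitney_u(c(1, 2), c(3, 4), "less")
  expect_equal(t1$p_value, 1 / 6)
  expect_equal(t1$statistic, 0)
  expect_identical(t1$method, "exact")

  t2 <- mann_whitney_u(1, 2, "less")
  expect_equal(t2$p_value, 1 / 2)

  t3 <- mann_whitney_u(5, 5, "two.sided")
  expect_equal(t3$p_value, 1)
  expect_identical(t3$method, "approximate")
})

test_that("exact Mann-Whitney p equals brute-force enumeration", {
  set.seed(32)
  for (sizes in list(c(3, 3), c(4, 3), c(5, 4), c(7, 7))) {
    for (rep in 1:3) {
      x <- round(rnorm(sizes[1], 0.5, 1), 6)
      y <- round(rnorm(sizes[2], 0, 1), 6)
      if (anyDuplicated(c(x, y))) next
      for (alt in c("greater", "less", "two.sided")) {
        got <- mann_whitney_u(x, y, alt)
        expect_identical(got$method, "exact")
        expect_equal(got$p_value, mann_whitney_enum_p(x, y, alt),
                     tolerance = 1e-12,
                     label = sprintf("MW n=%d m=%d alt=%s",
                                     sizes[1], sizes[2], alt))
      }
    }
  }
})

test_that("exact tests hold their size at the study's sample sizes", {
  set.seed(33)
  n_rep <- 2000
  rej_w <- 0
  for (i in seq_len(n_rep)) {
    d <- rnorm(12)
    rej_w <- rej_w + (wilcoxon_signed_rank(d, "greater")$p_value <= 0.05)
  }
  expect_gte(rej_w / n_rep, 0.03)
  expect_lte(rej_w / n_rep, 0.07)

  rej_u <- 0
  for (i in seq_len(n_rep)) {
    x <- rnorm(12); y <- rnorm(11)
    rej_u <- rej_u + (mann_whitney_u(x, y, "greater",
                                     exact_max = 23L)$p_value <= 0.05)
  }
  expect_gte(rej_u / n_rep, 0.03)
  expect_lte(rej_u / n_rep, 0.07)
})

test_that("linear trend test identifies flat and perfectly linear series", {
  flat <- linear_trend_test(c(0, 12, 24, 36), rep(30, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1)

  lin <- linear_trend_test(c(0, 12, 24, 36), 30 + 0.1 * c(0, 12, 24, 36))
  expect_equal(lin$slope, 0.1, tolerance = 1e-10)
  expect_lt(lin$p_value, 1e-10)

  expect_error(linear_trend_test(c(1, 1, 1), c(1, 2, 3)),
               class = "arc_domain_error")
})

test_that("infection screen reproduces the study's exclusion logic", {
  mk <- function(leuk2, neut2, t1, t2, leuk1 = 16000, neut1 = 6000) {
    data.frame(animal_id = "P1", group = "control",
               occasion = c("M1", "M2"),
               body_weight_kg = c(14, 16), temp_c = c(t1, t2),
               leukocytes_per_ul = c(leuk1, leuk2),
               neutrophils_per_ul = c(neut1, neut2),
               lymphocytes_per_ul = c(9000, 9000),
               monocytes_per_ul = c(700, 700))
  }
  # the study's excluded piglet: leukocytosis + 1.2 degC rise
  out <- infection_screen(mk(32690, 23341, 39.2, 40.4))
  expect_identical(out$decision, "exclude")
  # everything normal
  expect_identical(infection_screen(mk(17000, 6000, 39.2, 39.2))$decision,
                   "include")
  # hematology outlier without fever is kept (as in the study)
  expect_identical(infection_screen(mk(32690, 23341, 39.2, 39.3))$decision,
                   "include")
  # fever alone is kept
  expect_identical(infection_screen(mk(17000, 6000, 39.0, 40.5))$decision,
                   "include")
  # missing panel errors
  expect_error(infection_screen(mk(NA, 6000, 39.2, 39.2)),
               class = "arc_missing_data_error")
})

test_that("urine completeness requires leak-free collections at both occasions", {
  mk <- function(leak_m1 = 0L, leak_m2 = 0L, drop_m2 = FALSE) {
    u <- data.frame(animal_id = "P1",
                    occasion = rep(c("M1", "M2"), each = 2),
                    start_h = c(0, 2, 0, 2), end_h = c(2, 4, 2, 4),
                    volume_ml = 50, conc_ug_per_ml = 100,
                    leaked = c(leak_m1, 0L, leak_m2, 0L))
    if (drop_m2) u <- u[u$occasion == "M1", ]
    u
  }
  expect_true(urine_completeness_filter(mk())$eligible)
  expect_false(urine_completeness_filter(mk(leak_m1 = 1L))$eligible)
  expect_false(urine_completeness_filter(mk(leak_m2 = 1L))$eligible)
  expect_false(urine_completeness_filter(mk(leak_m1 = 1L,
                                            leak_m2 = 1L))$eligible)
  expect_false(urine_completeness_filter(mk(drop_m2 = TRUE))$eligible)
})

test_that("group summaries use linearly interpolated quartiles", {
  s <- summarize_group(c(1, 2, 3), rep("control", 3), rep("M1", 3))
  expect_equal(s$median, 2)
  s4 <- summarize_group(c(1, 2, 3, 4), rep("control", 4), rep("M1", 4))
  expect_equal(s4$p25, 1.75)
  expect_equal(s4$median, 2.5)
  expect_equal(s4$p75, 3.25)
  s1 <- summarize_group(7, "treatment", "M2")
  expect_equal(s1$p25, 7)
  expect_equal(s1$p75, 7)
  expect_warning(summarize_group(NA_real_, "control", "M1"))
})
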
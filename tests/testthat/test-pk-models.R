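test_that("closed-form prediction matches hand-computed values", {
  p1 <- pk_parameters(cl_tot = 4, v1 = 500)
  expect_equal(predict_concentration(p1, 7.5, 0), 15)
  # k = 4 * 60 / 500 = 0.48 1/h
  expect_equal(predict_concentration(p1, 7.5, 1), 15 * exp(-0.48),
               tolerance = 1e-12)
  tt <- paper_schedule()
  cc <- predict_concentration(p1, 7.5, tt)
  expect_true(all(diff(cc) < 0))
  expect_lt(predict_concentration(p1, 7.5, 100), 1e-15)
})

test_that("the 2-compartment model degenerates to 1-compartment", {
  tt <- c(0, paper_schedule())
  p1 <- pk_parameters(4, 500)
  p2 <- pk_parameters(4, 500, q = 1e-9, v2 = 1e-3)
  c1 <- predict_concentration(p1, 7.5, tt)
  c2 <- predict_concentration(p2, 7.5, tt)
  expect_equal(c2, c1, tolerance = 1e-8)
})

test_that("invalid parameters and times are rejected", {
  expect_error(pk_parameters(-1, 500), class = "arc_domain_error")
  expect_error(pk_parameters(4, 500, q = 3, v2 = NULL),
               class = "arc_domain_error")
  p <- pk_parameters(4, 500)
  expect_error(predict_concentration(p, 7.5, -1),
               class = "arc_domain_error")
})

test_that("exclude_blq drops censored records and demands enough data", {
  tt <- paper_schedule()
  p <- pk_parameters(4, 500)
  cc <- predict_concentration(p, 7.5, tt)
  blq <- c(rep(FALSE, 10), TRUE, TRUE)
  prof <- plasma_profile("A1", "control", "M1", "amikacin", 7.5, 14,
                         tt, ifelse(blq, NA, cc), blq, lloq = 0.5)
  out <- exclude_blq(prof)
  expect_length(out$time, 10)
  expect_identical(out$time, tt[1:10])

  clean <- plasma_profile("A1", "control", "M1", "amikacin", 7.5, 14,
                          tt, cc, lloq = 0.5)
  expect_identical(exclude_blq(clean)$time, clean$time)

  allblq <- plasma_profile("A1", "control", "M1", "amikacin", 7.5, 14,
                           tt, rep(NA_real_, 12), rep(TRUE, 12), lloq = 0.5)
  expect_error(exclude_blq(allblq), class = "arc_insufficient_data_error")
})

test_that("noise-free fits recover the generating parameters to 0.1%", {
  truth <- pk_parameters(3.55, 250, 3.0, 140)
  prof <- make_profile(truth, 64.7)
  fit <- fit_profile(prof, 2, "proportional")
  est <- fit$params
  rel <- abs(c(est$cl_tot / 3.55, est$v1 / 250, est$q / 3.0,
               est$v2 / 140) - 1)
  expect_lt(max(rel), 1e-3)
  expect_true(fit$converged)
  # zero-residual limit: residual scale collapses
  expect_lt(fit$sigma, 1e-6)
  expect_true(all(fit$cv_pct < 1e-2))
})

test_that("noise-free 1-compartment proportional fit has sigma ~ 0", {
  prof <- make_profile(pk_parameters(4, 500), 7.5)
  fit <- fit_profile(prof, 1, "proportional")
  expect_lt(fit$sigma, 1e-6)
  expect_equal(fit$params$cl_tot, 4, tolerance = 1e-6)
})

test_that("a 3-point profile cannot support a 2-compartment fit", {
  p <- pk_parameters(4, 500)
  tt <- c(0.5, 2, 6)
  prof <- plasma_profile("A1", "control", "M1", "iohexol", 64.7, 14,
                         tt, predict_concentration(p, 64.7, tt), lloq = 0.25)
  expect_error(fit_profile(prof, 2), class = "arc_insufficient_data_error")
})

test_that("derived parameters obey the dose-conservation identity", {
  # AUC = D * 1e6 / (CL * 60): worked examples at Table-style magnitudes
  f1 <- fit_profile(make_profile(pk_parameters(4.06, 320, 4, 210), 7.5,
                                 analyte = "amikacin", lloq = 0.5), 2)
  expect_equal(derived_parameters(f1)$auc_inf,
               7.5e6 / (f1$params$cl_tot * 60), tolerance = 1e-12)
  expect_equal(f1$auc_inf, 30788, tolerance = 1e-3)
  expect_equal(f1$vss, f1$params$v1 + f1$params$v2)

  f2 <- fit_profile(make_profile(pk_parameters(4.25, 247, 4.25, 165),
                                 64.7), 2)
  expect_equal(f2$auc_inf, 253725, tolerance = 1e-3)

  f3 <- fit_profile(make_profile(pk_parameters(4, 500), 7.5), 1)
  expect_equal(derived_parameters(f3)$vss, f3$params$v1)
})

test_that("fitted AUC decreases as true clearance increases (noise-free)", {
  aucs <- vapply(c(3, 3.6, 4.2, 5), function(cl) {
    fit_profile(make_profile(pk_parameters(cl, 250, cl, 140), 64.7), 2)$auc_inf
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("2-compartment fits keep alpha > beta and vss >= v1", {
  set.seed(42)
  for (i in 1:5) {
    truth <- pk_parameters(3.5 * exp(rnorm(1, 0, 0.1)), 250, 3, 140)
    prof <- make_profile(truth, 64.7, noise_sd = 0.07)
    fit <- fit_profile(prof, 2)
    m <- arcfluid:::macro_constants(fit$params, 64.7)
    expect_gt(m$rates[1], m$rates[2])
    expect_gte(fit$vss, fit$params$v1)
  }
})

test_that("median clearance bias is below 1% at 5% proportional noise", {
  set.seed(77)
  truth <- pk_parameters(3.7, 228, 3.7, 152)
  bias <- vapply(1:200, function(i) {
    fit <- fit_profile(make_profile(truth, 64.7, noise_sd = 0.05), 2)
    fit$params$cl_tot / 3.7 - 1
  }, numeric(1))
  expect_lt(abs(stats::median(bias)), 0.01)
})

test_that("select_model keeps 2-comp on well-conditioned biexponential data", {
  set.seed(8)
  prof <- make_profile(pk_parameters(3.55, 250, 3.0, 140), 64.7,
                       noise_sd = 0.05)
  fit <- select_model(prof)
  expect_identical(fit$params$n_compartments, 2L)
  expect_identical(fit$error_model, "proportional")
})

test_that("select_model falls back to 1-comp on degenerate profiles", {
  set.seed(9)
  # data generated monoexponentially: the 2-comp fit cannot resolve the
  # peripheral compartment and its precision collapses
  prof <- make_profile(pk_parameters(3.7, 380), 64.7, noise_sd = 0.07)
  fit <- select_model(prof, cv_threshold = 50)
  expect_identical(fit$params$n_compartments, 1L)
  expect_true(all(fit$cv_pct <= 50))

  pah <- make_profile(pk_parameters(24, 490), 10, noise_sd = 0.05,
                      analyte = "pah")
  fitp <- select_model(pah)
  if (fitp$params$n_compartments == 1L) {
    expect_identical(fitp$error_model, "additive")
  }
})

test_that("amikacin profiles always get the 2-compartment model", {
  set.seed(10)
  # even near-monoexponential amikacin data keeps the structural model
  prof <- make_profile(pk_parameters(3.6, 520), 7.5, noise_sd = 0.07,
                       analyte = "amikacin", lloq = 0.5)
  fit <- select_model(prof)
  expect_identical(fit$params$n_compartments, 2L)
})
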
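test_that("simulation is deterministic given the seed", {
  a <- simulate_cohort(small_config(), seed = 42)
  b <- simulate_cohort(small_config(), seed = 42)
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(small_config(), seed = 43)
  expect_false(identical(a$dataset$plasma, c$dataset$plasma))
})

test_that("config validation rejects bad fields and values", {
  expect_error(simulation_config(nonsense = 1), class = "arc_config_error")
  expect_error(simulation_config(n_control = 0), class = "arc_config_error")
  expect_error(simulation_config(v1_frac = 1.2), class = "arc_config_error")
  expect_error(simulation_config(analytes_included = "caffeine"),
               class = "arc_config_error")
  cfg <- simulation_config(analytes = list(iohexol = list(lloq = 0.1)))
  expect_equal(cfg$analytes$iohexol$lloq, 0.1)
  expect_equal(cfg$analytes$amikacin$lloq, 0.5)
})

test_that("the null configuration yields identical fitted clearances", {
  cfg <- small_config(
    analytes_included = "iohexol",
    analytes = list(iohexol = list(
      residual = list(model = "proportional", sd = 0),
      retest_cv = 0, fluid_cl_mean = 1, fluid_cl_sd = 0,
      fluid_vss_mult = 1)),
    vss_retest_cv = 0)
  sim <- simulate_cohort(cfg, seed = 5)
  rep <- run_analysis(sim)
  w <- merge(rep$fits[rep$fits$occasion == "M1", c("animal_id", "cl_tot")],
             rep$fits[rep$fits$occasion == "M2", c("animal_id", "cl_tot")],
             by = "animal_id")
  expect_equal(w$cl_tot.y / w$cl_tot.x, rep(1, nrow(w)), tolerance = 1e-6)
})

test_that("PAH profiles are right-censored before 4 h at defaults", {
  sim <- simulate_cohort(simulation_config(n_control = 4L,
                                           n_treatment = 4L), seed = 6)
  p <- sim$dataset$plasma
  pah_late <- p[p$analyte == "pah" & p$time_h >= 4, ]
  expect_true(all(pah_late$blq == 1))
  # but the early phase is quantifiable
  pah_early <- p[p$analyte == "pah" & p$time_h > 0 & p$time_h <= 0.5, ]
  expect_true(all(pah_early$blq == 0))
})

test_that("urinary mass balance holds without measurement noise", {
  cfg <- small_config(urine_conc_cv = 0, uo_cv = 0)
  sim <- simulate_cohort(cfg, seed = 7)
  u <- sim$dataset$urine
  p <- sim$dataset$plasma
  for (id in unique(u$animal_id)) {
    for (occ in c("M1", "M2")) {
      ui <- u[u$animal_id == id & u$occasion == occ, ]
      bw <- p$body_weight_kg[p$animal_id == id & p$occasion == occ][1]
      ae <- cumulative_excretion(ui, bw)$ae
      expect_lte(ae, cfg$fe_pah * cfg$analytes$pah$dose + 1e-9)
    }
  }
})

test_that("generated truth matches the configured effect structure", {
  # no-noise generator: treatment M2/M1 clearance ratio equals the fluid
  # multiplier exactly when retest dispersion is off
  cfg <- small_config(
    analytes_included = "amikacin",
    analytes = list(amikacin = list(retest_cv = 0, fluid_cl_sd = 0)),
    vss_retest_cv = 0)
  sim <- simulate_cohort(cfg, seed = 8)
  tr <- sim$truth
  for (id in unique(tr$animal_id)) {
    w <- tr[tr$animal_id == id, ]
    ratio <- w$cl_tot[w$occasion == "M2"] / w$cl_tot[w$occasion == "M1"]
    expected <- if (w$group[1] == "treatment") 1.14 else 1
    expect_equal(ratio, expected, tolerance = 1e-12)
  }
})

test_that("anomaly injection closes the loop with the screening filters", {
  sim <- simulate_cohort(small_config(), seed = 9)
  d <- inject_anomalies(sim$dataset,
                        list(leukocytosis = "P02",
                             urine_leak = list(animal_id = "P03",
                                               occasion = "M1")))
  rows <- d$animals[d$animals$animal_id == "P02", ]
  expect_identical(infection_screen(rows)$decision, "exclude")
  ok_rows <- d$animals[d$animals$animal_id == "P01", ]
  expect_identical(infection_screen(ok_rows)$decision, "include")

  flt <- urine_completeness_filter(d$urine[d$urine$animal_id == "P03", ])
  expect_false(flt$eligible)
  expect_match(flt$reason, "M1")

  expect_identical(inject_anomalies(sim$dataset, list()), sim$dataset)
  expect_error(inject_anomalies(sim$dataset, list(alien = 1)),
               class = "arc_config_error")
})
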
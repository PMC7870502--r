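test_that("write/read round-trips a simulated dataset value-for-value", {
  sim <- simulate_cohort(small_config(), seed = 11)
  dir <- withr::local_tempdir()
  write_study_tables(sim$dataset, dir)
  back <- read_study_tables(dir)
  for (tb in c("plasma", "urine", "animals", "hematocrit")) {
    expect_equal(back[[tb]], sim$dataset[[tb]], tolerance = 0,
                 ignore_attr = TRUE)
  }
})

test_that("a leaked urine interval survives the round trip", {
  sim <- simulate_cohort(small_config(), seed = 11)
  d <- inject_anomalies(sim$dataset,
                        list(urine_leak = list(animal_id = "P01",
                                               occasion = "M1")))
  dir <- withr::local_tempdir()
  write_study_tables(d, dir)
  back <- read_study_tables(dir)
  row <- back$urine[back$urine$animal_id == "P01" &
                    back$urine$occasion == "M1", ]
  expect_identical(sum(row$leaked), 1L)
})

test_that("an empty dataset writes headers-only files and reads back empty", {
  d <- study_dataset(plasma = data.frame(
    animal_id = character(0), group = character(0), occasion = character(0),
    analyte = character(0), dose_mg_per_kg = numeric(0),
    body_weight_kg = numeric(0), time_h = numeric(0),
    conc_ug_per_ml = numeric(0), blq = integer(0),
    lloq_ug_per_ml = numeric(0)))
  dir <- withr::local_tempdir()
  write_study_tables(d, dir)
  expect_identical(length(readLines(file.path(dir, "plasma.csv"))), 1L)
  back <- read_study_tables(dir)
  expect_identical(nrow(back$plasma), 0L)
})

test_that("'<LLOQ' concentration cells are parsed as censored records", {
  dir <- withr::local_tempdir()
  hdr <- paste(c("animal_id", "group", "occasion", "analyte",
                 "dose_mg_per_kg", "body_weight_kg", "time_h",
                 "conc_ug_per_ml", "blq", "lloq_ug_per_ml"),
               collapse = ",")
  rows <- c("A1,control,M1,iohexol,64.7,14,1,25.2,0,0.25",
            "A1,control,M1,iohexol,64.7,14,10,<LLOQ,0,0.25")
  writeLines(c(hdr, rows), file.path(dir, "plasma.csv"))
  d <- read_study_tables(dir)
  expect_identical(d$plasma$blq, c(0L, 1L))
  expect_true(is.na(d$plasma$conc_ug_per_ml[2]))
  expect_equal(d$plasma$conc_ug_per_ml[1], 25.2)
})

test_that("schema and validation errors carry provenance", {
  dir <- withr::local_tempdir()
  writeLines(c("animal_id,conc_ug_per_ml", "A1,3.2"),
             file.path(dir, "plasma.csv"))
  expect_error(read_study_tables(dir), "time_h",
               class = "arc_schema_error")

  sim <- simulate_cohort(small_config(), seed = 2)
  bad <- sim$dataset
  bad$urine$volume_ml[3] <- -5
  expect_error(validate_study_dataset(bad), "row 3",
               class = "arc_validation_error")

  bad2 <- sim$dataset
  bad2$plasma$time_h[2] <- -1
  expect_error(validate_study_dataset(bad2), "negative time",
               class = "arc_validation_error")
})

test_that("profiles() splits the plasma table with metadata intact", {
  sim <- simulate_cohort(small_config(analytes_included = "iohexol"),
                         seed = 5)
  pr <- profiles(sim$dataset)
  expect_length(pr, 6 * 2)          # 6 animals x 2 occasions
  p <- pr[[1]]
  expect_s3_class(p, "plasma_profile")
  expect_identical(length(p$time), 13L)      # pre-dose + 12 samples
  expect_identical(p$dose_mg_per_kg, 64.7)
})

test_that("profile construction enforces ordering and positivity", {
  expect_error(plasma_profile("A", "control", "M1", "iohexol", 64.7, 14,
                              c(1, 1), c(2, 1), lloq = 0.25),
               class = "arc_validation_error")
  expect_error(plasma_profile("A", "control", "M1", "iohexol", -1, 14,
                              1, 2, lloq = 0.25),
               class = "arc_validation_error")
  expect_error(plasma_profile("A", "control", "M1", "caffeine", 64.7, 14,
                              1, 2, lloq = 0.25),
               class = "arc_validation_error")
})
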
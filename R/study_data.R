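# Domain data model and tabular I/O.
#
# A study dataset is a list of four data frames mirroring the on-disk CSV
# schema; plasma_profile objects are the per-animal x analyte x occasion
# concentration-time series consumed by the fitting machinery.

PLASMA_COLS <- c("animal_id", "group", "occasion", "analyte", "dose_mg_per_kg",
                 "body_weight_kg", "time_h", "conc_ug_per_ml", "blq",
                 "lloq_ug_per_ml")
URINE_COLS <- c("animal_id", "occasion", "start_h", "end_h", "volume_ml",
                "conc_ug_per_ml", "leaked")
ANIMAL_COLS <- c("animal_id", "group", "occasion", "body_weight_kg", "temp_c",
                 "leukocytes_per_ul", "neutrophils_per_ul",
                 "lymphocytes_per_ul", "monocytes_per_ul")
HCT_COLS <- c("animal_id", "time_since_fluid_start_h", "hct_pct")

#' Construct a plasma concentration-time profile
#'
#' One animal x analyte x measurement-occasion series after an IV bolus,
#' with dose and assay metadata. Concentrations below the lower limit of
#' quantification (LLOQ) are kept as censored records (`blq = TRUE`,
#' `conc = NA`); a pre-dose record at `time = 0` may be present but is
#' never passed to the fitter.
#'
#' @param animal_id Animal identifier.
#' @param group `"control"` or `"treatment"`.
#' @param occasion Measurement occasion, `"M1"` or `"M2"`.
#' @param analyte One of `"iohexol"`, `"pah"`, `"amikacin"`.
#' @param dose_mg_per_kg IV bolus dose (mg/kg body weight).
#' @param body_weight_kg Body weight at the occasion (kg).
#' @param time Sampling times since dose (h), strictly increasing.
#' @param conc Plasma concentrations (ug/mL); `NA` for censored records.
#' @param blq Logical, record below the LLOQ.
#' @param lloq Assay lower limit of quantification (ug/mL).
#' @return An object of class `plasma_profile`.
#' @export
plasma_profile <- function(animal_id, group, occasion, analyte,
                           dose_mg_per_kg, body_weight_kg,
                           time, conc, blq = rep(FALSE, length(time)),
                           lloq) {
  arc_check(analyte %in% ANALYTES,
            sprintf("unknown analyte '%s'", analyte), "arc_validation_error")
  arc_check(occasion %in% OCCASIONS,
            sprintf("unknown occasion '%s'", occasion), "arc_validation_error")
  arc_check(is.numeric(dose_mg_per_kg) && dose_mg_per_kg > 0,
            "dose_mg_per_kg must be > 0", "arc_validation_error")
  arc_check(is.numeric(lloq) && lloq > 0, "lloq must be > 0",
            "arc_validation_error")
  arc_check(all(time >= 0), "sampling times must be >= 0",
            "arc_validation_error")
  arc_check(!is.unsorted(time, strictly = TRUE),
            "sampling times must be strictly increasing",
            "arc_validation_error")
  arc_check(length(conc) == length(time) && length(blq) == length(time),
            "time, conc and blq must have equal length", "arc_validation_error")
  blq <- as.logical(blq)
  arc_check(all(conc[!blq & time > 0] >= 0, na.rm = TRUE),
            "quantifiable concentrations must be >= 0", "arc_validation_error")
  structure(
    list(animal_id = animal_id, group = group, occasion = occasion,
         analyte = analyte, dose_mg_per_kg = dose_mg_per_kg,
         body_weight_kg = body_weight_kg,
         time = as.numeric(time), conc = as.numeric(conc), blq = blq,
         lloq = lloq),
    class = "plasma_profile")
}

#' @export
print.plasma_profile <- function(x, ...) {
  cat(sprintf("<plasma_profile> %s %s %s (%s): %d records, dose %.3g mg/kg, LLOQ %.3g ug/mL\n",
              x$animal_id, x$analyte, x$occasion, x$group,
              length(x$time), x$dose_mg_per_kg, x$lloq))
  invisible(x)
}

# Number of quantifiable post-dose records.
n_quantifiable <- function(profile) {
  sum(!profile$blq & profile$time > 0 & !is.na(profile$conc))
}

#' Assemble a study dataset
#'
#' Bundles the four study tables (plasma concentration-time records, timed
#' urine collections, per-occasion animal records, hematocrit series) and
#' validates them against the schema invariants.
#'
#' @param plasma,urine,animals,hematocrit Data frames following the
#'   column schema documented in [read_study_tables()].
#' @return A validated object of class `study_dataset`.
#' @export
study_dataset <- function(plasma, urine = NULL, animals = NULL,
                          hematocrit = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                        cols))
    df
  }
  d <- structure(
    list(plasma = plasma,
         urine = urine %||% empty(URINE_COLS),
         animals = animals %||% empty(ANIMAL_COLS),
         hematocrit = hematocrit %||% empty(HCT_COLS)),
    class = "study_dataset")
  validate_study_dataset(d)
  d
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(paste0("<study_dataset> %d plasma records (%d profiles), ",
                     "%d urine intervals, %d animal-occasion rows, ",
                     "%d hematocrit rows\n"),
              nrow(x$plasma),
              nrow(unique(x$plasma[, c("animal_id", "analyte", "occasion")])),
              nrow(x$urine), nrow(x$animals), nrow(x$hematocrit)))
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    arc_abort(sprintf("%s is missing required column(s): %s", what,
                      paste(missing, collapse = ", ")),
              "arc_schema_error")
  }
}

row_check <- function(ok, what, msg) {
  if (!all(ok)) {
    arc_abort(sprintf("%s: %s (row %s)", what, msg,
                      paste(which(!ok), collapse = ", ")),
              "arc_validation_error")
  }
}

#' Validate a study dataset
#'
#' Checks the schema and row-level invariants: non-negative times, volumes
#' and counts, strictly increasing sampling times per profile,
#' non-overlapping urine intervals, hematocrit within (0, 100). Failures
#' raise classed errors (`arc_schema_error`, `arc_validation_error`)
#' carrying the offending row index.
#'
#' @param d A `study_dataset`.
#' @return `d`, invisibly, if valid.
#' @export
validate_study_dataset <- function(d) {
  arc_check(inherits(d, "study_dataset"), "not a study_dataset",
            "arc_validation_error")
  check_columns(d$plasma, PLASMA_COLS, "plasma table")
  check_columns(d$urine, URINE_COLS, "urine table")
  check_columns(d$animals, ANIMAL_COLS, "animals table")
  check_columns(d$hematocrit, HCT_COLS, "hematocrit table")

  p <- d$plasma
  if (nrow(p) > 0) {
    row_check(p$time_h >= 0, "plasma table", "negative time_h")
    row_check(p$dose_mg_per_kg > 0, "plasma table", "non-positive dose")
    row_check(p$lloq_ug_per_ml > 0, "plasma table", "non-positive LLOQ")
    row_check(p$blq %in% c(0, 1), "plasma table", "blq must be 0/1")
    quant <- p$blq == 0 & p$time_h > 0
    row_check(!quant | (!is.na(p$conc_ug_per_ml) & p$conc_ug_per_ml >= 0),
              "plasma table", "quantifiable record lacks concentration >= 0")
    key <- interaction(p$animal_id, p$analyte, p$occasion, drop = TRUE)
    for (idx in split(seq_len(nrow(p)), key)) {
      tt <- p$time_h[idx]
      if (is.unsorted(tt, strictly = TRUE)) {
        arc_abort(sprintf(
          "plasma table: times not strictly increasing within profile (rows %s)",
          paste(idx, collapse = ", ")), "arc_validation_error")
      }
    }
  }
  u <- d$urine
  if (nrow(u) > 0) {
    row_check(u$start_h >= 0, "urine table", "negative start_h")
    row_check(u$end_h > u$start_h, "urine table", "end_h must exceed start_h")
    row_check(u$volume_ml >= 0, "urine table", "negative volume")
    row_check(is.na(u$conc_ug_per_ml) | u$conc_ug_per_ml >= 0,
              "urine table", "negative concentration")
    row_check(u$leaked %in% c(0, 1), "urine table", "leaked must be 0/1")
    key <- interaction(u$animal_id, u$occasion, drop = TRUE)
    for (idx in split(seq_len(nrow(u)), key)) {
      o <- idx[order(u$start_h[idx])]
      if (length(o) > 1 &&
          any(u$start_h[o][-1] < u$end_h[o][-length(o)] - 1e-9)) {
        arc_abort(sprintf(
          "urine table: overlapping intervals within animal/occasion (rows %s)",
          paste(idx, collapse = ", ")), "arc_validation_error")
      }
    }
  }
  a <- d$animals
  if (nrow(a) > 0) {
    cnt <- c("leukocytes_per_ul", "neutrophils_per_ul", "lymphocytes_per_ul",
             "monocytes_per_ul")
    for (col in cnt) {
      row_check(is.na(a[[col]]) | a[[col]] >= 0, "animals table",
                sprintf("negative %s", col))
    }
  }
  h <- d$hematocrit
  if (nrow(h) > 0) {
    row_check(h$hct_pct > 0 & h$hct_pct < 100, "hematocrit table",
              "hct_pct must lie in (0, 100)")
  }
  invisible(d)
}

#' Extract plasma profiles from a dataset
#'
#' Splits the plasma table into one [plasma_profile()] per
#' animal x analyte x occasion.
#'
#' @param d A validated `study_dataset`.
#' @return A list of `plasma_profile` objects.
#' @export
profiles <- function(d) {
  p <- d$plasma
  if (nrow(p) == 0) return(list())
  key <- interaction(p$animal_id, p$analyte, p$occasion, drop = TRUE)
  lapply(split(seq_len(nrow(p)), key), function(idx) {
    r <- p[idx, ]
    plasma_profile(
      animal_id = r$animal_id[1], group = r$group[1],
      occasion = r$occasion[1], analyte = r$analyte[1],
      dose_mg_per_kg = r$dose_mg_per_kg[1],
      body_weight_kg = r$body_weight_kg[1],
      time = r$time_h, conc = r$conc_ug_per_ml,
      blq = r$blq == 1, lloq = r$lloq_ug_per_ml[1])
  })
}

# Format doubles so that read(write(x)) reproduces x bit-for-bit.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

write_one_csv <- function(df, path, num_cols) {
  out <- df
  for (col in intersect(num_cols, names(out))) out[[col]] <- fmt_num(out[[col]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    arc_abort(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
              "arc_io_error")
  }
}

read_one_csv <- function(path, required, what) {
  if (!file.exists(path)) {
    arc_abort(sprintf("%s file not found: '%s'", what, path), "arc_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  check_columns(df, required, what)
  df
}

study_paths <- function(dir) {
  list(plasma = file.path(dir, "plasma.csv"),
       urine = file.path(dir, "urine.csv"),
       animals = file.path(dir, "animals.csv"),
       hematocrit = file.path(dir, "hematocrit.csv"))
}

#' Read study tables from CSV
#'
#' Reads the four study CSV files (`plasma.csv`, `urine.csv`,
#' `animals.csv`, `hematocrit.csv`) from a directory and returns a
#' validated [study_dataset()]. All times are in hours, concentrations in
#' ug/mL; below-LLOQ plasma cells are empty with `blq = 1`.
#'
#' @param dir Directory containing the CSV files. `urine.csv`,
#'   `animals.csv` and `hematocrit.csv` are optional; a missing file
#'   yields an empty table.
#' @return A `study_dataset`.
#' @export
read_study_tables <- function(dir) {
  paths <- study_paths(dir)
  plasma <- read_one_csv(paths$plasma, PLASMA_COLS, "plasma table")
  # assay exports sometimes write "<LLOQ" in the concentration cell
  cc <- plasma$conc_ug_per_ml
  if (is.character(cc)) {
    below <- grepl("^\\s*<", cc)
    plasma$conc_ug_per_ml <- suppressWarnings(as.numeric(cc))
    plasma$conc_ug_per_ml[below] <- NA_real_
    plasma$blq[below] <- 1L
  }
  opt <- function(path, cols, what) {
    if (file.exists(path)) read_one_csv(path, cols, what) else NULL
  }
  study_dataset(
    plasma = plasma,
    urine = opt(paths$urine, URINE_COLS, "urine table"),
    animals = opt(paths$animals, ANIMAL_COLS, "animals table"),
    hematocrit = opt(paths$hematocrit, HCT_COLS, "hematocrit table"))
}

#' Write study tables to CSV
#'
#' Inverse of [read_study_tables()]: writes the four tables so that
#' re-reading reproduces the dataset value-for-value (doubles are printed
#' with 17 significant digits).
#'
#' @param d A validated `study_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(d, dir) {
  validate_study_dataset(d)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- study_paths(dir)
  write_one_csv(d$plasma, paths$plasma,
                c("dose_mg_per_kg", "body_weight_kg", "time_h",
                  "conc_ug_per_ml", "lloq_ug_per_ml"))
  write_one_csv(d$urine, paths$urine,
                c("start_h", "end_h", "volume_ml", "conc_ug_per_ml"))
  write_one_csv(d$animals, paths$animals,
                c("body_weight_kg", "temp_c", "leukocytes_per_ul",
                  "neutrophils_per_ul", "lymphocytes_per_ul",
                  "monocytes_per_ul"))
  write_one_csv(d$hematocrit, paths$hematocrit,
                c("time_since_fluid_start_h", "hct_pct"))
  invisible(dir)
}
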
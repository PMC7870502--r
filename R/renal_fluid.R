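# Urinary excretion, renal clearance, urine output and plasma-volume
# physiology. Units: Ae mg/kg, AUC ng.h/mL, CL_R mL/min/kg, urine output
# mL/kg/h, hematocrit %.

#' Cumulative urinary excretion
#'
#' Sums amount excreted over timed collections (volume x concentration at
#' each collection point), indexed to body weight:
#' `ae = sum(volume_i * conc_i) / 1000 / body_weight` (mg/kg). A
#' collection is complete only when no interval leaked.
#'
#' @param intervals Data frame of urine intervals with columns `start_h`,
#'   `end_h`, `volume_ml`, `conc_ug_per_ml`, `leaked`.
#' @param body_weight Body weight (kg).
#' @return A list of class `excretion_summary`: `ae` (mg/kg),
#'   `collection_span` (h), `complete`.
#' @export
cumulative_excretion <- function(intervals, body_weight) {
  arc_check(body_weight > 0, "body_weight must be > 0")
  if (nrow(intervals) == 0) {
    return(structure(list(ae = 0, collection_span = 0, complete = TRUE),
                     class = "excretion_summary"))
  }
  arc_check(all(intervals$volume_ml >= 0),
            "urine volumes must be >= 0", "arc_validation_error")
  arc_check(all(intervals$conc_ug_per_ml >= 0, na.rm = TRUE),
            "urine concentrations must be >= 0", "arc_validation_error")
  ae <- sum(intervals$volume_ml * intervals$conc_ug_per_ml) / 1e3 /
    body_weight
  structure(
    list(ae = ae,
         collection_span = max(intervals$end_h) - min(intervals$start_h),
         complete = !any(intervals$leaked == 1)),
    class = "excretion_summary")
}

#' Renal clearance from urinary recovery
#'
#' `CL_R = Ae / AUC_0->inf`, converted to mL/min/kg:
#' `cl_r = ae * 1e6 / auc_inf / 60` with `ae` in mg/kg and `auc_inf` in
#' ng.h/mL. Whenever `ae <= dose`, `cl_r <= cl_tot` by construction.
#'
#' @param ae Cumulative amount excreted (mg/kg).
#' @param auc_inf Total exposure (ng.h/mL), > 0.
#' @return Renal clearance (mL/min/kg).
#' @export
renal_clearance <- function(ae, auc_inf) {
  arc_check(is.numeric(auc_inf) && auc_inf > 0, "auc_inf must be > 0")
  arc_check(is.numeric(ae) && ae >= 0, "ae must be >= 0")
  ae * 1e6 / auc_inf / 60
}

#' Urine output rate
#'
#' Total collected volume over the collection span, per kg body weight.
#' Requires a complete (leak-free) collection spanning more than 0 h.
#'
#' @param intervals Urine interval data frame (see
#'   [cumulative_excretion()]).
#' @param body_weight Body weight (kg).
#' @return Urine output (mL/kg/h).
#' @export
urine_output_rate <- function(intervals, body_weight) {
  arc_check(body_weight > 0, "body_weight must be > 0")
  arc_check(nrow(intervals) > 0, "no urine intervals",
            "arc_insufficient_data_error")
  if (any(intervals$leaked == 1)) {
    arc_abort("incomplete urine collection (leaked interval present)",
              "arc_incomplete_collection_error")
  }
  span <- max(intervals$end_h) - min(intervals$start_h)
  arc_check(span > 0, "collection span must be > 0")
  sum(intervals$volume_ml) / span / body_weight
}

#' Plasma-volume change from hematocrit (van Beaumont)
#'
#' Percent change in plasma volume under the constant red-cell-volume
#' assumption:
#' \deqn{\%\Delta P = \frac{100}{100 - H_1} \cdot
#'       \frac{100 (H_1 - H_2)}{H_2}}
#' with `h1` the hematocrit before fluid administration and `h2` at a
#' later time. Positive values indicate hemodilution (`h2 < h1`).
#'
#' @param h1,h2 Hematocrit values in percent, each in (0, 100).
#' @return Signed percent change in plasma volume.
#' @export
plasma_volume_change <- function(h1, h2) {
  arc_check(all(h1 > 0 & h1 < 100) && all(h2 > 0 & h2 < 100),
            "hematocrit values must lie in (0, 100)")
  (100 / (100 - h1)) * (100 * (h1 - h2) / h2)
}
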
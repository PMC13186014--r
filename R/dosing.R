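#' Noradrenaline infusion preparation
#'
#' Models the standard syringe-pump preparation: a drug vial diluted with
#' 0.9% sodium chloride in a luer-lock syringe. The institutional default
#' is a 5 mg / 5 mL noradrenaline vial diluted with 45 mL of saline to
#' 50 mL, giving 0.1 mg/mL.
#'
#' @param drug_mass_mg Drug mass in the vial, mg (> 0).
#' @param vial_volume_ml Vial volume, mL (> 0).
#' @param diluent_volume_ml Diluent volume, mL (>= 0).
#' @return An `infusion_preparation`: drug mass, vial/diluent/total volumes
#'   and the resulting concentration in mg/mL.
#' @examples
#' prepare_infusion()  # 5 mg to 50 mL -> 0.1 mg/mL
#' @export
prepare_infusion <- function(drug_mass_mg = 5, vial_volume_ml = 5,
                             diluent_volume_ml = 45) {
  drug_mass_mg <- check_num(drug_mass_mg, "drug_mass_mg", min = 0,
                            open_min = TRUE, required = TRUE)
  vial_volume_ml <- check_num(vial_volume_ml, "vial_volume_ml", min = 0,
                              open_min = TRUE, required = TRUE)
  diluent_volume_ml <- check_num(diluent_volume_ml, "diluent_volume_ml",
                                 min = 0, required = TRUE)
  total <- vial_volume_ml + diluent_volume_ml
  structure(
    list(drug_mass_mg = drug_mass_mg,
         vial_volume_ml = vial_volume_ml,
         diluent_volume_ml = diluent_volume_ml,
         total_volume_ml = total,
         concentration_mg_per_ml = drug_mass_mg / total),
    class = "infusion_preparation")
}

#' @export
print.infusion_preparation <- function(x, ...) {
  cat(sprintf("%g mg in %g mL (vial %g mL + diluent %g mL) -> %g mg/mL\n",
              x$drug_mass_mg, x$total_volume_ml, x$vial_volume_ml,
              x$diluent_volume_ml, x$concentration_mg_per_ml))
  invisible(x)
}

#' Pump rate for a target dose
#'
#' @param dose_mg_per_h Target dose in mg/h (>= 0).
#' @param concentration_mg_per_ml Infusion concentration in mg/mL (> 0);
#'   0.1 mg/mL is the institutional standard preparation.
#' @return Pump rate in mL/h.
#' @export
dose_to_rate <- function(dose_mg_per_h, concentration_mg_per_ml = 0.1) {
  dose_mg_per_h <- check_num(dose_mg_per_h, "dose_mg_per_h", min = 0,
                             required = TRUE)
  concentration_mg_per_ml <- check_num(concentration_mg_per_ml,
                                       "concentration_mg_per_ml", min = 0,
                                       open_min = TRUE, required = TRUE)
  dose_mg_per_h / concentration_mg_per_ml
}

#' Convert a noradrenaline dose between mg/h and ug/kg/min
#'
#' The score's bands use the institutional mg/h standardisation; the shock
#' literature uses weight-based ug/kg/min. `convert_dose()` bridges the
#' two: `mg/h * 1000 / 60 / weight` in the forward direction.
#'
#' @param dose Dose value, in the unit named by `from` (>= 0).
#' @param weight_kg Patient weight in kg (> 0).
#' @param from Unit of `dose`: `"mg_h"` (default) converts to ug/kg/min,
#'   `"ug_kg_min"` converts back to mg/h.
#' @return The converted dose.
#' @examples
#' convert_dose(0.42, 70)                       # 0.1 ug/kg/min
#' convert_dose(0.1, 70, from = "ug_kg_min")    # 0.42 mg/h
#' @export
convert_dose <- function(dose, weight_kg, from = c("mg_h", "ug_kg_min")) {
  from <- match.arg(from)
  dose <- check_num(dose, "dose", min = 0, required = TRUE)
  weight_kg <- check_num(weight_kg, "weight_kg", min = 0, open_min = TRUE,
                         required = TRUE)
  if (from == "mg_h") dose * 1000 / 60 / weight_kg
  else dose * 60 * weight_kg / 1000
}

#' Literature shock-severity band for a weight-based noradrenaline dose
#'
#' Pragmatic dose thresholds from the shock literature: mild
#' (< 0.1 ug/kg/min), moderate (0.1-0.3), severe (0.3-0.5), refractory
#' (> 0.5). The cutoffs are empirical and lack universal consensus;
#' boundary points are assigned to the higher-severity side. Doses above
#' the printed 1.0 ug/kg/min ceiling stay "refractory" with an
#' `above_printed_range` flag. This banding is informational only: the
#' COSTAS points use the institutional mg/h bands
#' ([score_noradrenaline()]).
#'
#' @param dose_ug_kg_min Dose in ug/kg/min (>= 0).
#' @return A list with `label` (one of mild/moderate/severe/refractory)
#'   and `flags`.
#' @export
shock_band <- function(dose_ug_kg_min) {
  dose <- check_num(dose_ug_kg_min, "dose_ug_kg_min", min = 0, required = TRUE)
  label <- if (dose < 0.1) "mild"
           else if (dose < 0.3) "moderate"
           else if (dose < 0.5) "severe"
           else "refractory"
  list(label = label,
       flags = if (dose > 1.0) "above_printed_range" else character())
}

#' Full dosing summary for one patient
#'
#' @param dose_mg_per_h Noradrenaline dose in mg/h.
#' @param weight_kg Patient weight in kg (may be `NA`: the weight-based
#'   conversion and shock band are then omitted).
#' @param concentration_mg_per_ml Infusion concentration, default the
#'   institutional 0.1 mg/mL.
#' @param table Scoring table for the COSTAS points.
#' @return A list: pump rate (mL/h), weight-based dose (ug/kg/min) with
#'   shock band, and the COSTAS noradrenaline `parameter_score`.
#' @export
dosing_summary <- function(dose_mg_per_h, weight_kg = NA,
                           concentration_mg_per_ml = 0.1,
                           table = costas_table()) {
  out <- list(
    dose_mg_per_h = check_num(dose_mg_per_h, "dose_mg_per_h", min = 0,
                              required = TRUE),
    concentration_mg_per_ml = concentration_mg_per_ml,
    rate_ml_per_h = dose_to_rate(dose_mg_per_h, concentration_mg_per_ml),
    score = score_noradrenaline(dose_mg_per_h, table))
  if (length(weight_kg) == 1L && !is.na(weight_kg)) {
    wkm <- convert_dose(dose_mg_per_h, weight_kg)
    out$dose_ug_kg_min <- wkm
    out$shock_band <- shock_band(wkm)
  }
  out
}
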
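#' Validate a raw patient mapping into a `patient_record`
#'
#' Checks one patient's clinical snapshot against the physical ranges the
#' score expects and returns a normalised record. Units are fixed: age in
#' whole years, BMI in kg/m^2 (computed from `height_m` and `weight_kg` when
#' `bmi` is absent), eGFR in mL/min, P/F ratio in mmHg, PEEP in cm H2O,
#' noradrenaline in mg/h, weight in kg.
#'
#' Mechanical-ventilation fields (`pf_ratio`, `peep`) must be supplied
#' together or not at all; their joint absence means the patient is not
#' mechanically ventilated and both ventilation parameters later score zero.
#' Intracranial arterial atherosclerosis may be given either as
#' `iaa_stenosis_pct` (percent stenosis of the worst intracranial vessel,
#' 0-100) or as a pre-adjudicated logical `iaa_detected` (stenosis >= 50%
#' seen on angiography, TCD, or intraoperatively). Fractional ages are
#' floored to whole years.
#'
#' @param raw Named list (or single-row data frame) of field name -> value.
#'   Must contain `patient_id`, `age`, `smoker`, `egfr`,
#'   `noradrenaline_mg_per_h`, a BMI source, and an IAA source.
#' @return An object of class `patient_record`: a named list with fields
#'   `patient_id`, `age`, `smoker`, `iaa_stenosis_pct` (may be `NA`),
#'   `iaa_detected`, `bmi`, `egfr`, `ventilated`, `pf_ratio`, `peep`,
#'   `noradrenaline_mg_per_h`, `ai_risk_prob` (may be `NA`), `weight_kg`
#'   (may be `NA`), `aneurysm_treatment` (may be `NA`).
#' @examples
#' rec <- validate_record(list(
#'   patient_id = "P01", age = 70, smoker = TRUE, iaa_stenosis_pct = 60,
#'   bmi = 27, egfr = 50, pf_ratio = 250, peep = 8,
#'   noradrenaline_mg_per_h = 1.0, ai_risk_prob = 0.6, weight_kg = 80))
#' rec$bmi
#' @export
validate_record <- function(raw) {
  if (is.data.frame(raw)) {
    if (nrow(raw) != 1L)
      abort_validation("validate_record() expects a single patient (one row)")
    raw <- as.list(raw)
  }
  if (!is.list(raw) || is.null(names(raw)))
    abort_validation("patient input must be a named list or one-row data frame")

  get <- function(field) {
    v <- raw[[field]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) NULL else v
  }

  patient_id <- get("patient_id")
  if (is.null(patient_id))
    abort_validation("missing required field: patient_id", field = "patient_id")
  patient_id <- as.character(patient_id)

  age <- check_num(get("age"), "age", min = 0, required = TRUE)
  age <- as.integer(floor(age))

  smoker <- check_flag(get("smoker"), "smoker", required = TRUE)

  iaa_pct <- check_num(get("iaa_stenosis_pct"), "iaa_stenosis_pct",
                       min = 0, max = 100)
  iaa_detected <- check_flag(get("iaa_detected"), "iaa_detected")
  if (is.null(iaa_pct) && is.null(iaa_detected))
    abort_validation(
      "one of iaa_stenosis_pct or iaa_detected is required",
      field = "iaa_stenosis_pct")
  if (!is.null(iaa_pct)) iaa_detected <- iaa_pct >= 50

  bmi <- check_num(get("bmi"), "bmi", min = 0, open_min = TRUE)
  height_m <- check_num(get("height_m"), "height_m", min = 0, open_min = TRUE)
  weight_kg <- check_num(get("weight_kg"), "weight_kg", min = 0, open_min = TRUE)
  if (is.null(bmi)) {
    if (is.null(height_m) || is.null(weight_kg))
      abort_validation("bmi (or height_m and weight_kg) is required",
                       field = "bmi")
    bmi <- weight_kg / height_m^2
  }

  egfr <- check_num(get("egfr"), "egfr", min = 0, required = TRUE)

  pf <- check_num(get("pf_ratio"), "pf_ratio", min = 0, open_min = TRUE)
  peep <- check_num(get("peep"), "peep", min = 0)
  if (xor(is.null(pf), is.null(peep)))
    abort_validation(
      "pf_ratio and peep must be supplied together (both present when ventilated, both absent otherwise)",
      field = if (is.null(pf)) "pf_ratio" else "peep")
  ventilated <- !is.null(pf)

  nor <- check_num(get("noradrenaline_mg_per_h"), "noradrenaline_mg_per_h",
                   min = 0, required = TRUE)

  ai <- check_num(get("ai_risk_prob"), "ai_risk_prob", min = 0, max = 1)

  treatment <- get("aneurysm_treatment")
  if (is.null(treatment)) treatment <- get("treatment")
  if (!is.null(treatment)) {
    treatment <- as.character(treatment)
    if (!treatment %in% c("surgical", "endovascular"))
      abort_validation(
        sprintf("aneurysm_treatment must be 'surgical' or 'endovascular', got '%s'",
                treatment),
        field = "aneurysm_treatment")
  }

  structure(
    list(
      patient_id = patient_id,
      age = age,
      smoker = smoker,
      iaa_stenosis_pct = if (is.null(iaa_pct)) NA_real_ else iaa_pct,
      iaa_detected = iaa_detected,
      bmi = bmi,
      egfr = egfr,
      ventilated = ventilated,
      pf_ratio = if (ventilated) pf else NA_real_,
      peep = if (ventilated) peep else NA_real_,
      noradrenaline_mg_per_h = nor,
      ai_risk_prob = if (is.null(ai)) NA_real_ else ai,
      weight_kg = if (is.null(weight_kg)) NA_real_ else weight_kg,
      aneurysm_treatment = if (is.null(treatment)) NA_character_ else treatment
    ),
    class = "patient_record"
  )
}

check_num <- function(value, field, min = -Inf, max = Inf,
                      open_min = FALSE, required = FALSE) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) {
    if (required)
      abort_validation(sprintf("missing required field: %s", field),
                       field = field)
    return(NULL)
  }
  value <- suppressWarnings(as.numeric(value))
  if (length(value) != 1L || is.na(value) || !is.finite(value))
    abort_validation(sprintf("%s must be a finite number", field),
                     field = field)
  low_ok <- if (open_min) value > min else value >= min
  if (!low_ok || value > max)
    abort_validation(
      sprintf("%s = %s is outside the physical range %s%s, %s]",
              field, format(value), if (open_min) "(" else "[",
              format(min), format(max)),
      field = field)
  value
}

check_flag <- function(value, field, required = FALSE) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) {
    if (required)
      abort_validation(sprintf("missing required field: %s", field),
                       field = field)
    return(NULL)
  }
  if (is.character(value))
    value <- switch(tolower(value),
                    "true" = TRUE, "t" = TRUE, "yes" = TRUE, "1" = TRUE,
                    "false" = FALSE, "f" = FALSE, "no" = FALSE, "0" = FALSE,
                    NA)
  if (is.numeric(value) && value %in% c(0, 1)) value <- as.logical(value)
  if (!is.logical(value) || length(value) != 1L || is.na(value))
    abort_validation(sprintf("%s must be TRUE/FALSE", field), field = field)
  value
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s>\n", x$patient_id))
  cat(sprintf("  age %d y | smoker %s | IAA >=50%%: %s\n",
              x$age, x$smoker, x$iaa_detected))
  cat(sprintf("  BMI %.1f | eGFR %.0f mL/min\n", x$bmi, x$egfr))
  if (x$ventilated)
    cat(sprintf("  ventilated: P/F %.0f mmHg, PEEP %.0f cm H2O\n",
                x$pf_ratio, x$peep))
  else cat("  not mechanically ventilated\n")
  cat(sprintf("  noradrenaline %.2f mg/h | AI risk %s\n",
              x$noradrenaline_mg_per_h,
              if (is.na(x$ai_risk_prob)) "-" else sprintf("%.2f", x$ai_risk_prob)))
  invisible(x)
}

#' @export
as.list.patient_record <- function(x, ...) unclass(x)

#' Convert patient records to a data frame
#'
#' @param x A `patient_record` or list of them.
#' @param ... Unused.
#' @return A data frame with one row per record and the record fields as
#'   columns.
#' @export
as.data.frame.patient_record <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.patient_record
#' @export
records_to_df <- function(x, ...) {
  if (inherits(x, "patient_record")) x <- list(x)
  do.call(rbind, lapply(x, as.data.frame))
}
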
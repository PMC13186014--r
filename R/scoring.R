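#' @title Per-parameter COSTAS scorers
#'
#' @description Each scorer maps one clinical quantity onto its point band
#' and returns a `parameter_score`: the parameter name, the points awarded,
#' the category label, and any transparency flags. Bands come from the
#' scoring table (see [costas_table()] for the shipped thresholds):
#' age >= 65 y, smoking, and intracranial stenosis >= 50% are one point
#' each; BMI (WHO classes) and eGFR (KDOQI risk classes) award up to two;
#' the P/F ratio (Berlin ARDS classes), PEEP, and the noradrenaline dose in
#' mg/h award up to three; the clustered AI vasospasm-risk probability
#' awards up to two.
#'
#' @param table Scoring table; defaults to the shipped [costas_table()].
#' @return A `parameter_score` object.
#' @name scorers
NULL

parameter_score <- function(parameter, points, label, flags = character()) {
  structure(list(parameter = parameter, points = as.integer(points),
                 label = label, flags = flags),
            class = "parameter_score")
}

#' @export
print.parameter_score <- function(x, ...) {
  cat(sprintf("%-14s %d point%s  (%s)%s\n", x$parameter, x$points,
              if (x$points == 1L) "" else "s", x$label,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

score_from_band <- function(parameter, value, table) {
  band <- match_band(table, parameter, value)
  parameter_score(parameter, band$points, band$label,
                  flags = band$flag[!is.na(band$flag)])
}

#' @rdname scorers
#' @param age Age in years (fractional ages are floored).
#' @export
score_age <- function(age, table = costas_table()) {
  age <- check_num(age, "age", min = 0, required = TRUE)
  score_from_band("age", floor(age), table)
}

#' @rdname scorers
#' @param smoker Logical: does the patient smoke cigarettes?
#' @export
score_smoking <- function(smoker, table = costas_table()) {
  smoker <- check_flag(smoker, "smoker", required = TRUE)
  score_from_band("smoking", as.numeric(smoker), table)
}

#' @rdname scorers
#' @param stenosis Percent stenosis of the worst intracranial vessel in
#'   0-100, or a logical for a pre-adjudicated "stenosis >= 50% detected"
#'   call (angiography, TCD, or intraoperative).
#' @export
score_iaa <- function(stenosis, table = costas_table()) {
  if (is.logical(stenosis)) {
    stenosis <- check_flag(stenosis, "iaa_detected", required = TRUE)
    stenosis <- if (stenosis) 50 else 0
  } else {
    stenosis <- check_num(stenosis, "iaa_stenosis_pct", min = 0, max = 100,
                          required = TRUE)
  }
  score_from_band("iaa", stenosis, table)
}

#' @rdname scorers
#' @param bmi Body-mass index in kg/m^2.
#' @export
score_bmi <- function(bmi, table = costas_table()) {
  bmi <- check_num(bmi, "bmi", min = 0, open_min = TRUE, required = TRUE)
  score_from_band("bmi", bmi, table)
}

#' @rdname scorers
#' @param egfr Estimated glomerular filtration rate in mL/min.
#' @export
score_gfr <- function(egfr, table = costas_table()) {
  egfr <- check_num(egfr, "egfr", min = 0, required = TRUE)
  score_from_band("gfr", egfr, table)
}

#' @rdname scorers
#' @param pf PaO2/FiO2 ratio in mmHg; ignored when not ventilated.
#' @param ventilated Logical: is the patient mechanically ventilated?
#'   A spontaneously breathing patient carries no ventilation burden and
#'   scores 0 on both ventilation parameters.
#' @export
score_pf_ratio <- function(pf, ventilated = TRUE, table = costas_table()) {
  if (!isTRUE(ventilated))
    return(parameter_score("pf_ratio", 0L, "not ventilated"))
  pf <- check_num(pf, "pf_ratio", min = 0, open_min = TRUE, required = TRUE)
  score_from_band("pf_ratio", pf, table)
}

#' @rdname scorers
#' @param peep Positive end-expiratory pressure in cm H2O; ignored when not
#'   ventilated.
#' @export
score_peep <- function(peep, ventilated = TRUE, table = costas_table()) {
  if (!isTRUE(ventilated))
    return(parameter_score("peep", 0L, "not ventilated"))
  peep <- check_num(peep, "peep", min = 0, required = TRUE)
  score_from_band("peep", peep, table)
}

#' @rdname scorers
#' @param dose Continuous noradrenaline infusion dose in mg/h (the
#'   institutional standardisation unit; see [convert_dose()] for the
#'   weight-based literature unit).
#' @export
score_noradrenaline <- function(dose, table = costas_table()) {
  dose <- check_num(dose, "noradrenaline_mg_per_h", min = 0, required = TRUE)
  score_from_band("noradrenaline", dose, table)
}

#' @rdname scorers
#' @param prob Predicted vasospasm-risk probability in \[0, 1\], e.g. from
#'   [predict_risk()].
#' @export
score_ai_risk <- function(prob, table = costas_table()) {
  prob <- check_num(prob, "ai_risk_prob", min = 0, max = 1, required = TRUE)
  score_from_band("ai_risk", prob, table)
}

#' Aggregate the nine parameter scores into the 0-18 COSTAS total
#'
#' @param record A validated [patient_record][validate_record()] (raw named
#'   lists are validated on the fly).
#' @param table Scoring table; defaults to the shipped [costas_table()].
#' @param model Optional fitted [risk model][train_risk_model()] used to
#'   compute `ai_risk_prob` when the record does not carry one (the record
#'   must then carry the risk-model features).
#' @return A `costas_result`: the patient id, the nine `parameter_score`s
#'   (named list in report order), the integer `total` in 0-18, the union
#'   of component flags, and the scoring-table version.
#' @examples
#' rec <- validate_record(list(
#'   patient_id = "P01", age = 70, smoker = TRUE, iaa_stenosis_pct = 0,
#'   bmi = 28, egfr = 50, pf_ratio = 250, peep = 8,
#'   noradrenaline_mg_per_h = 1.0, ai_risk_prob = 0.6))
#' total_score(rec)$total  # 8
#' @export
total_score <- function(record, table = costas_table(), model = NULL) {
  if (!inherits(record, "patient_record")) record <- validate_record(record)
  ai <- record$ai_risk_prob
  if (is.na(ai)) {
    if (is.null(model))
      abort_validation(
        "cannot score ai_risk: record has no ai_risk_prob and no risk model was supplied",
        field = "ai_risk_prob")
    ai <- predict_risk(model, as.list(record))
  }
  scores <- list(
    age           = score_age(record$age, table),
    smoking       = score_smoking(record$smoker, table),
    iaa           = if (is.na(record$iaa_stenosis_pct))
                      score_iaa(record$iaa_detected, table)
                    else score_iaa(record$iaa_stenosis_pct, table),
    bmi           = score_bmi(record$bmi, table),
    gfr           = score_gfr(record$egfr, table),
    pf_ratio      = score_pf_ratio(record$pf_ratio, record$ventilated, table),
    peep          = score_peep(record$peep, record$ventilated, table),
    noradrenaline = score_noradrenaline(record$noradrenaline_mg_per_h, table),
    ai_risk       = score_ai_risk(ai, table)
  )
  total <- sum(vapply(scores, `[[`, integer(1), "points"))
  structure(
    list(patient_id = record$patient_id,
         parameter_scores = scores,
         total = as.integer(total),
         flags = unique(unlist(lapply(scores, `[[`, "flags"))),
         table_version = attr(table, "version")),
    class = "costas_result")
}

#' @export
print.costas_result <- function(x, ...) {
  cat(sprintf("COSTAS score for %s (table %s)\n", x$patient_id, x$table_version))
  for (s in x$parameter_scores) print(s)
  cat(sprintf("TOTAL: %d / 18\n", x$total))
  if (length(x$flags))
    cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Score a whole cohort at once
#'
#' Vectorised scoring of a patient table: the banded lookup runs once per
#' parameter over all rows, so cohorts of tens of thousands score in
#' seconds.
#'
#' @param patients Data frame with one row per patient carrying the
#'   [validate_record()] fields (`pf_ratio`/`peep` may be `NA` for
#'   non-ventilated patients; `ai_risk_prob` is required unless `model` is
#'   given).
#' @param table Scoring table.
#' @param model Optional fitted risk model used to fill missing
#'   `ai_risk_prob` from the risk-feature columns.
#' @return A data frame with `patient_id`, one `<parameter>_points` column
#'   per parameter, `total`, and a `flags` column (";"-joined).
#' @export
score_patients <- function(patients, table = costas_table(), model = NULL) {
  if (!is.data.frame(patients) || nrow(patients) == 0L)
    abort_validation("patients must be a non-empty data frame")
  n <- nrow(patients)
  col <- function(nm) if (nm %in% names(patients)) patients[[nm]] else rep(NA, n)

  ai <- as.numeric(col("ai_risk_prob"))
  if (anyNA(ai)) {
    if (is.null(model))
      abort_validation("ai_risk_prob missing and no risk model supplied",
                       field = "ai_risk_prob")
    miss <- is.na(ai)
    ai[miss] <- predict_risk(model, patients[miss, , drop = FALSE])
  }

  iaa <- as.numeric(col("iaa_stenosis_pct"))
  if (anyNA(iaa)) {
    det <- col("iaa_detected")
    iaa[is.na(iaa)] <- ifelse(isTRUE_vec(det[is.na(iaa)]), 50, 0)
  }

  pf <- as.numeric(col("pf_ratio"))
  peep <- as.numeric(col("peep"))
  ventilated <- !is.na(pf) & !is.na(peep)

  vals <- list(
    age           = floor(as.numeric(col("age"))),
    smoking       = as.numeric(as.logical(col("smoker"))),
    iaa           = iaa,
    bmi           = as.numeric(col("bmi")),
    gfr           = as.numeric(col("egfr")),
    pf_ratio      = ifelse(ventilated, pf, NA_real_),
    peep          = ifelse(ventilated, peep, NA_real_),
    noradrenaline = as.numeric(col("noradrenaline_mg_per_h")),
    ai_risk       = ai
  )

  pts <- matrix(0L, nrow = n, ncol = length(vals),
                dimnames = list(NULL, names(vals)))
  flags <- rep("", n)
  for (p in names(vals)) {
    v <- vals[[p]]
    live <- !is.na(v)
    if (!any(live)) next
    band <- match_band(table, p, v[live])
    pts[live, p] <- band$points
    fl <- !is.na(band$flag)
    if (any(fl)) {
      tgt <- which(live)[fl]
      flags[tgt] <- ifelse(nchar(flags[tgt]) > 0L,
                           paste(flags[tgt], band$flag[fl], sep = ";"),
                           band$flag[fl])
    }
  }
  out <- data.frame(patient_id = as.character(col("patient_id")),
                    stringsAsFactors = FALSE)
  for (p in names(vals)) out[[paste0(p, "_points")]] <- pts[, p]
  out$total <- as.integer(rowSums(pts))
  out$flags <- flags
  out
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) !is.na(x) & x
  else if (is.numeric(x)) !is.na(x) & x == 1
  else !is.na(x) & tolower(as.character(x)) %in% c("true", "t", "yes", "1")
}
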
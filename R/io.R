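#' Read patient records from CSV or JSON
#'
#' Columns/keys are the [validate_record()] field names with fixed units
#' (mg/h, mL/min, cm H2O, mmHg) and a dot decimal separator. Every row is
#' validated; invalid rows do not abort the read but are collected with
#' their row number.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, or `"json"`. JSON may
#'   be a single patient object or an array of them.
#' @return A `costas_patient_set`: list with `records` (list of
#'   `patient_record`) and `errors` (data frame with `row`, `patient_id`,
#'   `message`).
#' @export
read_patients <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", json = "json",
                     abort_io(sprintf(
                       "cannot infer format from extension '.%s'; pass format=", ext)))
  }
  rows <- if (format == "csv") {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) abort_io(sprintf(
                     "failed to parse CSV %s: %s", path, conditionMessage(e))))
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  } else {
    doc <- tryCatch(jsonlite::read_json(path),
                    error = function(e) abort_io(sprintf(
                      "failed to parse JSON %s: %s", path, conditionMessage(e))))
    if (!is.null(names(doc))) list(doc) else doc
  }
  records <- list()
  errors <- data.frame(row = integer(), patient_id = character(),
                       message = character(), stringsAsFactors = FALSE)
  for (i in seq_along(rows)) {
    rec <- tryCatch(validate_record(rows[[i]]),
                    costas_validation_error = function(e) e)
    if (inherits(rec, "patient_record")) {
      records[[length(records) + 1L]] <- rec
    } else {
      pid <- rows[[i]][["patient_id"]]
      errors <- rbind(errors, data.frame(
        row = i, patient_id = if (is.null(pid)) NA_character_ else as.character(pid),
        message = conditionMessage(rec), stringsAsFactors = FALSE))
    }
  }
  structure(list(records = records, errors = errors),
            class = "costas_patient_set")
}

#' @export
print.costas_patient_set <- function(x, ...) {
  cat(sprintf("<costas_patient_set: %d record(s), %d row error(s)>\n",
              length(x$records), nrow(x$errors)))
  if (nrow(x$errors)) print(x$errors)
  invisible(x)
}

result_to_list <- function(result) {
  stopifnot(inherits(result, "costas_result"))
  list(
    patient_id = result$patient_id,
    table_version = result$table_version,
    parameters = lapply(result$parameter_scores, function(s)
      list(parameter = s$parameter, points = s$points, label = s$label,
           flags = as.list(s$flags))),
    total = result$total,
    flags = as.list(result$flags))
}

#' Render a scoring result as a report
#'
#' Deterministic: the same result renders byte-identically. The JSON form
#' round-trips through [parse_report()] back to the `costas_result`.
#'
#' @param result A [total_score()] result.
#' @param extras Optional named list appended verbatim under `"extras"`
#'   (e.g. screening triggers, dosing summary, timestamp).
#' @param format `"json"` (default) or `"text"`.
#' @return A single string.
#' @export
render_report <- function(result, extras = NULL, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- result_to_list(result)
    if (!is.null(extras)) doc$extras <- extras
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                         pretty = TRUE, digits = NA)))
  }
  lines <- c(
    sprintf("COSTAS report -- patient %s (table %s)",
            result$patient_id, result$table_version),
    vapply(result$parameter_scores, function(s)
      sprintf("  %-14s %d  %s%s", s$parameter, s$points, s$label,
              if (length(s$flags))
                paste0(" [", paste(s$flags, collapse = ", "), "]") else ""),
      character(1)),
    sprintf("  TOTAL          %d / 18", result$total))
  if (length(result$flags))
    lines <- c(lines, paste("  flags:", paste(result$flags, collapse = ", ")))
  paste(lines, collapse = "\n")
}

#' Reconstruct a `costas_result` from its JSON report
#'
#' @param json A JSON string produced by [render_report()].
#' @return The `costas_result`.
#' @export
parse_report <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  scores <- lapply(doc$parameters, function(s)
    parameter_score(s$parameter, s$points, s$label,
                    flags = as.character(unlist(s$flags))))
  structure(
    list(patient_id = doc$patient_id,
         parameter_scores = scores,
         total = as.integer(doc$total),
         flags = as.character(unlist(doc$flags)),
         table_version = doc$table_version),
    class = "costas_result")
}

#' Assemble a full triage report for one patient
#'
#' Combines the COSTAS score with the dosing summary (when a weight is
#' available), the risk probability and its band, any screening trigger
#' events, and the scale version into one document.
#'
#' @param record A validated [patient_record][validate_record()].
#' @param table Scoring table.
#' @param model Optional risk model for a missing `ai_risk_prob`.
#' @param triggers Optional data frame of [screen_observations()] events
#'   for this patient.
#' @param timestamp Report timestamp string; pass a fixed value for
#'   reproducible output.
#' @return A `costas_triage_report` list; render with [render_report()]
#'   via its `$result`, or serialise whole with [jsonlite::toJSON()].
#' @export
triage_report <- function(record, table = costas_table(), model = NULL,
                          triggers = NULL,
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  if (!inherits(record, "patient_record")) record <- validate_record(record)
  result <- total_score(record, table, model)
  dosing <- dosing_summary(record$noradrenaline_mg_per_h, record$weight_kg,
                           table = table)
  ai <- record$ai_risk_prob
  if (is.na(ai) && !is.null(model)) ai <- predict_risk(model, as.list(record))
  structure(
    list(patient_id = record$patient_id,
         result = result,
         risk_probability = ai,
         risk_band = result$parameter_scores$ai_risk$label,
         dosing = dosing,
         triggers = triggers,
         flags = result$flags,
         table_version = result$table_version,
         map_targets_mmHg = as.list(map_targets()),
         timestamp = timestamp),
    class = "costas_triage_report")
}

#' @export
print.costas_triage_report <- function(x, ...) {
  cat(render_report(x$result, format = "text"), "\n")
  cat(sprintf("  noradrenaline: %.2f mg/h = %.1f mL/h pump rate",
              x$dosing$dose_mg_per_h, x$dosing$rate_ml_per_h))
  if (!is.null(x$dosing$dose_ug_kg_min))
    cat(sprintf(" = %.3f ug/kg/min (%s shock band)",
                x$dosing$dose_ug_kg_min, x$dosing$shock_band$label))
  cat("\n")
  if (!is.null(x$triggers) && nrow(x$triggers))
    cat(sprintf("  %d screening trigger(s) on record\n", nrow(x$triggers)))
  invisible(x)
}
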
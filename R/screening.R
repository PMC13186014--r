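#' Protocol constants for induced hypertension
#'
#' Mean-arterial-pressure targets of the institutional vasospasm protocol:
#' induced hypertension at 80-90 mmHg on suspicion, permissive hypertension
#' above 100 mmHg if spasm persists. Recorded for reporting only; no
#' screening rule gates on them.
#'
#' @return Named numeric vector of MAP targets in mmHg.
#' @export
map_targets <- function() {
  c(induced_low = 80, induced_high = 90, persistent = 100)
}

#' A transcranial Doppler observation
#'
#' @param timestamp Time of the measurement (any orderable scalar; ISO
#'   strings work).
#' @param vessel Vessel label, e.g. `"MCA_left"`.
#' @param velocity_cm_s Mean flow velocity in cm/s (>= 0).
#' @return A `tcd_observation`.
#' @export
tcd_observation <- function(timestamp, vessel, velocity_cm_s) {
  velocity_cm_s <- check_num(velocity_cm_s, "velocity_cm_s", min = 0,
                             required = TRUE)
  structure(list(timestamp = timestamp, vessel = as.character(vessel),
                 velocity_cm_s = velocity_cm_s),
            class = "tcd_observation")
}

#' Suspected cerebral vasospasm from TCD velocities
#'
#' A flow acceleration raises suspicion when the mean velocity either
#' exceeds 190 cm/s (strict: exactly 190 does not trigger) or has risen by
#' at least 50% relative to the previous measurement of the same vessel
#' (inclusive at exactly 50%).
#'
#' @param current A [tcd_observation()].
#' @param previous The previous observation of the same vessel, or `NULL`
#'   when none exists (only the absolute rule then applies).
#' @return A list: `suspected` (logical), `rule` (`"absolute"`,
#'   `"relative"`, or `NA`), and `reason` (human-readable).
#' @examples
#' now <- tcd_observation("2026-01-02T08:00", "MCA_left", 150)
#' before <- tcd_observation("2026-01-01T08:00", "MCA_left", 100)
#' suspect_cvs(now, before)$suspected  # TRUE: +50% rise
#' @export
suspect_cvs <- function(current, previous = NULL) {
  stopifnot(inherits(current, "tcd_observation"))
  if (current$velocity_cm_s > 190)
    return(list(suspected = TRUE, rule = "absolute",
                reason = sprintf("velocity %.0f cm/s > 190 cm/s",
                                 current$velocity_cm_s)))
  if (!is.null(previous)) {
    stopifnot(inherits(previous, "tcd_observation"))
    if (!identical(previous$vessel, current$vessel))
      abort_validation(sprintf(
        "TCD observations compare different vessels: %s vs %s",
        previous$vessel, current$vessel), field = "vessel")
    if (previous$velocity_cm_s == 0)
      abort_validation(
        "relative velocity change is undefined for a previous velocity of 0 cm/s",
        field = "velocity_cm_s")
    rel <- (current$velocity_cm_s - previous$velocity_cm_s) /
      previous$velocity_cm_s
    if (rel >= 0.5)
      return(list(suspected = TRUE, rule = "relative",
                  reason = sprintf("velocity rose %.0f%% over previous measurement",
                                   100 * rel)))
  }
  list(suspected = FALSE, rule = NA_character_,
       reason = "below absolute and relative thresholds")
}

#' A neurological observation (GCS and focal deficits)
#'
#' Glasgow Coma Scale components are recorded individually, with motor
#' response on either side; the conventional total (3-15) uses the better
#' motor side. Focal deficits are the DCI-relevant ones: hemiparesis,
#' aphasia, apraxia, hemianopsia, neglect.
#'
#' @param timestamp Time of assessment.
#' @param gcs_eye Eye opening, 1-4.
#' @param gcs_verbal Verbal response, 1-5.
#' @param gcs_motor_left,gcs_motor_right Motor response per side, 1-6.
#' @param deficits Character vector of focal deficits present (subset of
#'   `c("hemiparesis", "aphasia", "apraxia", "hemianopsia", "neglect")`).
#' @param duration_hours Duration of the deterioration in hours (used on
#'   the current observation of a [dci_deterioration()] pair).
#' @param other_cause Logical: can the deterioration be attributed to
#'   another cause (by clinical assessment, CT/MRI, laboratory studies)?
#'   Taken as an adjudicated input, not computed.
#' @return A `neuro_observation` with the components, the derived `gcs_total`,
#'   the deficit set, duration and attribution flag.
#' @export
neuro_observation <- function(timestamp, gcs_eye, gcs_verbal,
                              gcs_motor_left, gcs_motor_right,
                              deficits = character(),
                              duration_hours = NA_real_,
                              other_cause = FALSE) {
  gcs_eye <- check_num(gcs_eye, "gcs_eye", min = 1, max = 4, required = TRUE)
  gcs_verbal <- check_num(gcs_verbal, "gcs_verbal", min = 1, max = 5,
                          required = TRUE)
  gcs_motor_left <- check_num(gcs_motor_left, "gcs_motor_left", min = 1,
                              max = 6, required = TRUE)
  gcs_motor_right <- check_num(gcs_motor_right, "gcs_motor_right", min = 1,
                               max = 6, required = TRUE)
  known <- c("hemiparesis", "aphasia", "apraxia", "hemianopsia", "neglect")
  deficits <- as.character(deficits)
  if (length(bad <- setdiff(deficits, known)))
    abort_validation(sprintf("unknown focal deficit(s): %s",
                             paste(bad, collapse = ", ")),
                     field = "deficits")
  total <- gcs_eye + gcs_verbal + max(gcs_motor_left, gcs_motor_right)
  structure(
    list(timestamp = timestamp,
         gcs_eye = gcs_eye, gcs_verbal = gcs_verbal,
         gcs_motor_left = gcs_motor_left, gcs_motor_right = gcs_motor_right,
         gcs_total = total,
         deficits = deficits,
         duration_hours = as.numeric(duration_hours),
         other_cause = isTRUE(other_cause)),
    class = "neuro_observation")
}

#' DCI-attributable clinical deterioration
#'
#' Delayed cerebral ischemia is called when, relative to baseline, a new
#' focal neurological deficit appears or the GCS drops by at least 2
#' points (on the total or on any single component, motor on either side
#' counted separately), the deterioration lasts at least one hour, and it
#' cannot be attributed to another cause.
#'
#' @param baseline,current [neuro_observation()]s; `current` must carry
#'   `duration_hours` and the adjudicated `other_cause` flag.
#' @return A list: `dci` (logical) and `reasons` (character vector of the
#'   triggered sub-criteria, empty when `dci` is `FALSE` for lack of any
#'   deficit).
#' @export
dci_deterioration <- function(baseline, current) {
  stopifnot(inherits(baseline, "neuro_observation"),
            inherits(current, "neuro_observation"))
  reasons <- character()
  new_def <- setdiff(current$deficits, baseline$deficits)
  if (length(new_def))
    reasons <- c(reasons, paste0("new focal deficit: ",
                                 paste(new_def, collapse = ", ")))
  if (baseline$gcs_total - current$gcs_total >= 2)
    reasons <- c(reasons, sprintf("GCS total dropped %d points",
                                  baseline$gcs_total - current$gcs_total))
  comps <- c("gcs_eye", "gcs_verbal", "gcs_motor_left", "gcs_motor_right")
  for (cmp in comps) {
    drop <- baseline[[cmp]] - current[[cmp]]
    if (drop >= 2)
      reasons <- c(reasons, sprintf("%s dropped %d points", cmp, drop))
  }
  if (!length(reasons))
    return(list(dci = FALSE, reasons = character()))
  if (is.na(current$duration_hours) || current$duration_hours < 1)
    return(list(dci = FALSE,
                reasons = "deterioration did not last >= 1 hour"))
  if (current$other_cause)
    return(list(dci = FALSE,
                reasons = "deterioration attributable to another cause"))
  list(dci = TRUE, reasons = reasons)
}

#' Screen a timestamped observation table for trigger events
#'
#' Runs [suspect_cvs()] over consecutive same-vessel TCD rows and
#' [dci_deterioration()] of each neurological row against the patient's
#' first (baseline) neurological row.
#'
#' @param obs Data frame of observations with columns `patient_id`,
#'   `timestamp`, `type` (`"tcd"` or `"neuro"`), and the type-specific
#'   columns (`vessel`, `velocity_cm_s`; `gcs_eye`, `gcs_verbal`,
#'   `gcs_motor_left`, `gcs_motor_right`, `deficits` (";"-joined),
#'   `duration_hours`, `other_cause`).
#' @return A data frame of trigger events: `patient_id`, `timestamp`,
#'   `event` (`"cvs_suspected"` or `"dci"`), `reason`.
#' @export
screen_observations <- function(obs) {
  if (!is.data.frame(obs)) abort_validation("obs must be a data frame")
  need <- c("patient_id", "timestamp", "type")
  if (length(miss <- setdiff(need, names(obs))))
    abort_validation(paste("observation table is missing columns:",
                           paste(miss, collapse = ", ")))
  events <- list()
  for (pid in unique(obs$patient_id)) {
    po <- obs[obs$patient_id == pid, , drop = FALSE]
    po <- po[order(po$timestamp), , drop = FALSE]

    tcd <- po[po$type == "tcd", , drop = FALSE]
    for (vessel in unique(tcd$vessel)) {
      vt <- tcd[tcd$vessel == vessel, , drop = FALSE]
      prev <- NULL
      for (i in seq_len(nrow(vt))) {
        cur <- tcd_observation(vt$timestamp[i], vt$vessel[i],
                               vt$velocity_cm_s[i])
        res <- suspect_cvs(cur, prev)
        if (res$suspected)
          events[[length(events) + 1L]] <- data.frame(
            patient_id = pid, timestamp = vt$timestamp[i],
            event = "cvs_suspected", reason = res$reason,
            stringsAsFactors = FALSE)
        prev <- cur
      }
    }

    neuro <- po[po$type == "neuro", , drop = FALSE]
    if (nrow(neuro) >= 2L) {
      mk <- function(i) neuro_observation(
        neuro$timestamp[i], neuro$gcs_eye[i], neuro$gcs_verbal[i],
        neuro$gcs_motor_left[i], neuro$gcs_motor_right[i],
        deficits = split_tokens(neuro$deficits[i]),
        duration_hours = if ("duration_hours" %in% names(neuro))
          neuro$duration_hours[i] else NA_real_,
        other_cause = if ("other_cause" %in% names(neuro))
          isTRUE_vec(neuro$other_cause[i]) else FALSE)
      baseline <- mk(1L)
      for (i in 2:nrow(neuro)) {
        res <- dci_deterioration(baseline, mk(i))
        if (res$dci)
          events[[length(events) + 1L]] <- data.frame(
            patient_id = pid, timestamp = neuro$timestamp[i],
            event = "dci", reason = paste(res$reasons, collapse = "; "),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(events))
    return(data.frame(patient_id = character(), timestamp = character(),
                      event = character(), reason = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, events)
}

split_tokens <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x)) character()
  else trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
}
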
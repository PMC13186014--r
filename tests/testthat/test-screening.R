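tcd <- function(v, vessel = "MCA_left", t = "2026-01-02T08:00") {
  tcd_observation(t, vessel, v)
}

test_that("TCD suspicion follows the absolute and relative velocity rules", {
  expect_true(suspect_cvs(tcd(195))$suspected)
  expect_identical(suspect_cvs(tcd(195))$rule, "absolute")

  r <- suspect_cvs(tcd(150), tcd(100))
  expect_true(r$suspected)
  expect_identical(r$rule, "relative")

  expect_false(suspect_cvs(tcd(150), tcd(120))$suspected)  # +25% only
  expect_false(suspect_cvs(tcd(190))$suspected)            # strict >190
  expect_true(suspect_cvs(tcd(120), tcd(80))$suspected)    # exactly +50%
  expect_false(suspect_cvs(tcd(119.9), tcd(80))$suspected)
})

test_that("a zero previous velocity is an error unless the absolute rule decides", {
  expect_error(suspect_cvs(tcd(150), tcd(0)),
               class = "costas_validation_error")
  expect_true(suspect_cvs(tcd(195), tcd(0))$suspected)
})

test_that("observations of different vessels cannot be compared", {
  expect_error(suspect_cvs(tcd(150), tcd(100, vessel = "MCA_right")),
               class = "costas_validation_error")
})

test_that("an unchanged velocity at or below 190 never raises suspicion", {
  for (v in seq(5, 190, by = 5))
    expect_false(suspect_cvs(tcd(v), tcd(v))$suspected)
})

neuro <- function(eye = 4, verbal = 5, ml = 6, mr = 6, deficits = character(),
                  duration = 2, other = FALSE, t = "2026-01-02T09:00") {
  neuro_observation(t, eye, verbal, ml, mr, deficits = deficits,
                    duration_hours = duration, other_cause = other)
}

test_that("GCS totals use the better motor side and stay in 3..15", {
  expect_equal(neuro()$gcs_total, 15)
  expect_equal(neuro(ml = 2, mr = 5)$gcs_total, 14)
  expect_equal(neuro_observation("t", 1, 1, 1, 1)$gcs_total, 3)
  expect_error(neuro_observation("t", 5, 5, 6, 6),
               class = "costas_validation_error")
  expect_error(neuro(deficits = "vertigo"), class = "costas_validation_error")
})

test_that("DCI needs a >=2-point drop or new deficit, >=1 h, no other cause", {
  base <- neuro()  # GCS 15

  # total drop of 2 (verbal 5 -> 3), 2 h, no other cause
  r <- dci_deterioration(base, neuro(verbal = 3))
  expect_true(r$dci)

  # single-component drop of 2 on the left motor side
  r <- dci_deterioration(base, neuro(ml = 4, duration = 1))
  expect_true(r$dci)
  expect_match(paste(r$reasons, collapse = " "), "motor_left")

  # too short
  expect_false(dci_deterioration(base, neuro(verbal = 3, duration = 0.5))$dci)

  # drop of only 1, no focal deficit
  expect_false(dci_deterioration(base, neuro(verbal = 4))$dci)

  # new focal deficit alone suffices
  expect_true(dci_deterioration(base, neuro(deficits = "aphasia"))$dci)

  # a deficit already present at baseline is not new
  base2 <- neuro(deficits = "hemiparesis", t = "2026-01-01T09:00")
  expect_false(dci_deterioration(base2, neuro(deficits = "hemiparesis"))$dci)
})

test_that("attribution to another cause vetoes DCI regardless of deficits", {
  base <- neuro()
  worst <- neuro(eye = 1, verbal = 1, ml = 1, mr = 1,
                 deficits = c("hemiparesis", "aphasia"), other = TRUE)
  expect_false(dci_deterioration(base, worst)$dci)
})

test_that("screening rules are pure: repeated calls give identical results", {
  cur <- tcd(150); prev <- tcd(100)
  expect_identical(suspect_cvs(cur, prev), suspect_cvs(cur, prev))
  base <- neuro(); det <- neuro(verbal = 3)
  expect_identical(dci_deterioration(base, det), dci_deterioration(base, det))
})

test_that("screen_observations emits trigger events per patient and vessel", {
  obs <- rbind(
    data.frame(patient_id = "A", timestamp = "2026-01-01T08:00", type = "tcd",
               vessel = "MCA_left", velocity_cm_s = 100,
               gcs_eye = NA, gcs_verbal = NA, gcs_motor_left = NA,
               gcs_motor_right = NA, deficits = NA, duration_hours = NA,
               other_cause = NA),
    data.frame(patient_id = "A", timestamp = "2026-01-02T08:00", type = "tcd",
               vessel = "MCA_left", velocity_cm_s = 160,
               gcs_eye = NA, gcs_verbal = NA, gcs_motor_left = NA,
               gcs_motor_right = NA, deficits = NA, duration_hours = NA,
               other_cause = NA),
    data.frame(patient_id = "B", timestamp = "2026-01-01T08:00", type = "neuro",
               vessel = NA, velocity_cm_s = NA,
               gcs_eye = 4, gcs_verbal = 5, gcs_motor_left = 6,
               gcs_motor_right = 6, deficits = "", duration_hours = NA,
               other_cause = FALSE),
    data.frame(patient_id = "B", timestamp = "2026-01-02T08:00", type = "neuro",
               vessel = NA, velocity_cm_s = NA,
               gcs_eye = 4, gcs_verbal = 3, gcs_motor_left = 6,
               gcs_motor_right = 6, deficits = "", duration_hours = 2,
               other_cause = FALSE))
  ev <- screen_observations(obs)
  expect_identical(nrow(ev), 2L)
  expect_setequal(ev$event, c("cvs_suspected", "dci"))
  expect_identical(ev$patient_id[ev$event == "cvs_suspected"], "A")
  expect_identical(ev$patient_id[ev$event == "dci"], "B")
})
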
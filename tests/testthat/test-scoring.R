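test_that("each scorer reproduces the printed bands, edges included", {
  cases <- list(
    # fun,                value,  points, label (NA = don't check)
    list(score_age,           65, 1L, ">=65 y"),
    list(score_age,           64, 0L, "<65 y"),
    list(score_age,           20, 0L, NA),
    list(score_smoking,     TRUE, 1L, "smoker"),
    list(score_smoking,    FALSE, 0L, "non-smoker"),
    list(score_iaa,           50, 1L, NA),
    list(score_iaa,           49, 0L, NA),
    list(score_iaa,         TRUE, 1L, NA),
    list(score_bmi,         22.0, 0L, "normal weight"),
    list(score_bmi,         27.0, 1L, "overweight"),
    list(score_bmi,         30.0, 2L, "obesity"),
    list(score_bmi,         24.9, 0L, "normal weight"),
    list(score_bmi,         29.9, 1L, "overweight"),
    list(score_gfr,           50, 0L, "low risk"),
    list(score_gfr,           35, 1L, "moderate risk"),
    list(score_gfr,           20, 2L, "high risk"),
    list(score_gfr,           45, 0L, "low risk"),
    list(score_pf_ratio,     250, 1L, "mild"),
    list(score_pf_ratio,     150, 2L, "moderate"),
    list(score_pf_ratio,      80, 3L, "severe"),
    list(score_pf_ratio,     400, 0L, NA),
    list(score_pf_ratio,     100, 3L, "severe"),   # gap closed conservatively
    list(score_pf_ratio,     300, 1L, "mild"),
    list(score_peep,           7, 1L, "mild"),
    list(score_peep,          12, 2L, "moderate"),
    list(score_peep,          18, 3L, "severe"),
    list(score_peep,           3, 0L, NA),
    list(score_noradrenaline,  0, 0L, "none"),
    list(score_noradrenaline, 0.5, 1L, "low risk"),
    list(score_noradrenaline, 1.0, 2L, "moderate risk"),
    list(score_noradrenaline, 2.0, 3L, "high risk"),
    list(score_noradrenaline, 0.55, 2L, NA),  # printed 0.5-0.6 gap
    list(score_noradrenaline, 1.95, 2L, NA),  # printed 1.9-2 gap
    list(score_ai_risk,     0.40, 0L, "low risk"),
    list(score_ai_risk,     0.60, 1L, "moderate risk"),
    list(score_ai_risk,     0.75, 2L, "high risk"),
    list(score_ai_risk,     0.50, 0L, "low risk"),
    list(score_ai_risk,     0.51, 1L, "moderate risk")
  )
  for (cs in cases) {
    s <- cs[[1]](cs[[2]])
    expect_identical(s$points, cs[[3]],
                     label = sprintf("%s(%s) points", s$parameter, cs[[2]]))
    if (!is.na(cs[[4]]))
      expect_identical(s$label, cs[[4]],
                       label = sprintf("%s(%s) label", s$parameter, cs[[2]]))
  }
})

test_that("values beyond the printed bands score with transparency flags", {
  expect_identical(score_bmi(17)$points, 0L)
  expect_identical(score_bmi(17)$flags, "underweight_unspecified")
  expect_identical(score_gfr(90)$points, 0L)
  expect_identical(score_gfr(90)$flags, "above_kdoqi_bands")
  expect_identical(score_peep(22)$points, 3L)
  expect_identical(score_peep(22)$flags, "peep_above_band")
  expect_length(score_pf_ratio(400)$flags, 0)
})

test_that("non-ventilated patients score zero on both ventilation parameters", {
  expect_identical(score_pf_ratio(NA, ventilated = FALSE)$points, 0L)
  expect_identical(score_peep(NA, ventilated = FALSE)$points, 0L)
})

test_that("the aggregate reproduces the 18 / 0 extremes and a hand-summed mixed case", {
  expect_identical(total_score(worst_case_patient())$total, 18L)
  expect_identical(total_score(best_case_patient())$total, 0L)

  mixed <- validate_record(list(
    patient_id = "mixed", age = 70, smoker = TRUE, iaa_stenosis_pct = 0,
    bmi = 28, egfr = 50, pf_ratio = 250, peep = 8,
    noradrenaline_mg_per_h = 1.0, ai_risk_prob = 0.60))
  res <- total_score(mixed)
  # 1 + 1 + 0 + 1 + 0 + 1 + 1 + 2 + 1
  expect_identical(res$total, 8L)
  expect_identical(
    vapply(res$parameter_scores, `[[`, integer(1), "points"),
    c(age = 1L, smoking = 1L, iaa = 0L, bmi = 1L, gfr = 0L,
      pf_ratio = 1L, peep = 1L, noradrenaline = 2L, ai_risk = 1L))
})

test_that("scoring without an AI probability needs a risk model", {
  rec <- best_case_patient()
  raw <- as.list(rec); raw$ai_risk_prob <- NULL
  err <- tryCatch(total_score(raw), condition = identity)
  expect_s3_class(err, "costas_validation_error")
  expect_match(conditionMessage(err), "ai_risk")
})

test_that("result flags are the union of component flags", {
  rec <- validate_record(list(
    patient_id = "flagged", age = 40, smoker = FALSE, iaa_stenosis_pct = 0,
    bmi = 17, egfr = 95, pf_ratio = 350, peep = 22,
    noradrenaline_mg_per_h = 0, ai_risk_prob = 0.1))
  res <- total_score(rec)
  expect_setequal(res$flags, c("underweight_unspecified",
                               "above_kdoqi_bands", "peep_above_band"))
})

test_that("vectorised cohort scoring agrees with per-record scoring", {
  df <- random_records_df(60, seed = 99)
  bulk <- score_patients(df)
  for (i in seq_len(nrow(df))) {
    res <- total_score(as.list(df[i, , drop = FALSE]))
    expect_identical(bulk$total[i], res$total)
  }
})
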
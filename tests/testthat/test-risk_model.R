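one_patient <- function(...) {
  modifyList(list(sex = "female", age = 55, hh_grade = 3L, fisher_grade = 3L,
                  bni_grade = 3L, comorbidities = "none",
                  anticoagulation = "none", op_duration_min = 120,
                  treatment = "endovascular"),
             list(...))
}

test_that("feature encoding is deterministic with a fixed schema", {
  p <- one_patient(comorbidities = "hypertension;pulmonary",
                   anticoagulation = "asa")
  x1 <- encode_features(p)
  x2 <- encode_features(p)
  expect_identical(x1, x2)
  expect_identical(colnames(x1), risk_feature_schema())
  expect_identical(ncol(x1), 14L)
  expect_equal(unname(x1[1, "com_hypertension"]), 1)
  expect_equal(unname(x1[1, "com_pulmonary"]), 1)
  expect_equal(unname(x1[1, "com_cardiovascular"]), 0)
  expect_equal(unname(x1[1, "ac_asa"]), 1)
})

test_that("'none' is the reference level: all its indicators are zero", {
  x <- encode_features(one_patient())
  ac <- x[1, c("ac_asa", "ac_doac", "ac_antiplatelet", "ac_combination")]
  expect_true(all(ac == 0))
  com <- x[1, c("com_hypertension", "com_cardiovascular", "com_pulmonary")]
  expect_true(all(com == 0))
})

test_that("unknown category levels and broken grades error naming the field", {
  err <- tryCatch(encode_features(one_patient(anticoagulation = "heparin")),
                  condition = identity)
  expect_s3_class(err, "costas_validation_error")
  expect_match(conditionMessage(err), "anticoagulation")

  expect_error(encode_features(one_patient(sex = "unknown")),
               class = "costas_validation_error")
  expect_error(encode_features(one_patient(hh_grade = 6)),
               class = "costas_validation_error")
  expect_error(encode_features(one_patient(fisher_grade = 5)),
               class = "costas_validation_error")
  expect_error(
    encode_features(one_patient(comorbidities = "none;hypertension")),
    class = "costas_validation_error")
})

test_that("training is reproducible and guards its preconditions", {
  coh <- generate_cohort(balanced_spec(200, seed = 21))
  m1 <- train_risk_model(coh, seed = 5)
  m2 <- train_risk_model(coh, seed = 5)
  expect_identical(m1$holdout_accuracy, m2$holdout_accuracy)
  expect_identical(m1$cv_accuracies, m2$cv_accuracies)
  newp <- one_patient()
  expect_identical(predict_risk(m1, newp), predict_risk(m2, newp))
  # and prediction itself is deterministic after fit
  expect_identical(predict_risk(m1, newp), predict_risk(m1, newp))

  single <- coh; single$cvs <- 0L
  expect_error(train_risk_model(single), class = "costas_validation_error")
  expect_error(train_risk_model(coh[1:10, ]), class = "costas_validation_error")
})

test_that("a planted signal is learned: holdout beats the no-information rate", {
  coh <- generate_cohort(balanced_spec(500, seed = 33))
  m <- train_risk_model(coh, seed = 9)
  nir <- max(mean(coh$cvs), 1 - mean(coh$cvs))
  expect_gt(m$holdout_accuracy, nir)
  expect_gt(m$cv_mean, nir)
})

test_that("with labels independent of features, CV sits near the majority rate", {
  coh <- generate_cohort(balanced_spec(400, seed = 13, effects = c()))
  m <- train_risk_model(coh, seed = 2)
  majority <- max(mean(coh$cvs), 1 - mean(coh$cvs))
  expect_lt(abs(m$cv_mean - majority), 0.10)
})

test_that("predictions are probabilities and separate the planted groups", {
  coh <- generate_cohort(balanced_spec(500, seed = 44))
  m <- train_risk_model(coh, seed = 3)
  p <- predict_risk(m, coh)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p[coh$cvs == 1]), mean(p[coh$cvs == 0]))
  # banding never errors on model output
  for (pp in p[1:50]) expect_s3_class(score_ai_risk(pp), "parameter_score")
})

test_that("a separable toy problem is classified perfectly", {
  train <- separable_cohort(120, seed = 1)
  test <- separable_cohort(80, seed = 2)
  m <- train_risk_model(train, seed = 4)
  ev <- evaluate_model(m, test)
  expect_equal(ev$accuracy, 1.0)
})

test_that("accuracy recomputed from the confusion counts matches", {
  coh <- generate_cohort(balanced_spec(300, seed = 55))
  m <- train_risk_model(coh[1:200, ], seed = 6)
  ev <- evaluate_model(m, coh[201:300, ])
  expect_equal(ev$accuracy,
               sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_identical(sum(ev$confusion), 100L)
  expect_error(evaluate_model(m, coh[0, ]), class = "costas_validation_error")
})

test_that("a fitted model survives a text-file round trip", {
  coh <- generate_cohort(balanced_spec(150, seed = 66))
  m <- train_risk_model(coh, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  save_risk_model(m, path)
  back <- load_risk_model(path)
  newp <- one_patient(age = 72, hh_grade = 4L)
  expect_identical(predict_risk(back, newp), predict_risk(m, newp))
})
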
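#' Feature schema of the vasospasm-risk model
#'
#' The risk model predicts symptomatic vasospasm from admission and
#' early-treatment data: sex, age, Hunt & Hess grade (1-5), Fisher grade
#' (1-4), BNI grade (1-5), comorbidities (arterial hypertension,
#' cardiovascular disease, pulmonary disease, or none), anticoagulation
#' (ASA, DOAC, antiplatelet, combination, or none), duration of the
#' operation or intervention, and treatment modality (surgical clipping vs
#' endovascular coiling). Categorical fields are one-hot encoded against a
#' "none"/reference level, ordinal grades stay integer, and the two
#' continuous fields (age, operation duration) are standardised with
#' training-set statistics.
#'
#' @return Character vector: the encoded column names, in order.
#' @export
risk_feature_schema <- function() {
  c("sex_male", "age", "hh_grade", "fisher_grade", "bni_grade",
    "com_hypertension", "com_cardiovascular", "com_pulmonary",
    "ac_asa", "ac_doac", "ac_antiplatelet", "ac_combination",
    "op_duration_min", "treatment_endovascular")
}

comorbidity_levels <- c("hypertension", "cardiovascular", "pulmonary")
anticoagulation_levels <- c("asa", "doac", "antiplatelet", "combination")

#' Validate a risk-feature table
#'
#' @param features Data frame (or single named list) with columns `sex`
#'   (`"male"`/`"female"`), `age`, `hh_grade` (1-5), `fisher_grade` (1-4),
#'   `bni_grade` (1-5), `comorbidities` (";"-joined subset of
#'   hypertension/cardiovascular/pulmonary, or `"none"`),
#'   `anticoagulation` (asa/doac/antiplatelet/combination/none),
#'   `op_duration_min` (> 0), and `treatment` or `aneurysm_treatment`
#'   (`"surgical"`/`"endovascular"`).
#' @return The features as a normalised data frame.
#' @export
validate_risk_features <- function(features) {
  if (!is.data.frame(features)) features <- as.data.frame(features[!vapply(features, is.null, logical(1))],
                                                          stringsAsFactors = FALSE)
  need <- c("sex", "age", "hh_grade", "fisher_grade", "bni_grade",
            "comorbidities", "anticoagulation", "op_duration_min")
  if (length(miss <- setdiff(need, names(features))))
    abort_validation(paste("risk features missing columns:",
                           paste(miss, collapse = ", ")),
                     field = miss[1])
  if (!"treatment" %in% names(features)) {
    if ("aneurysm_treatment" %in% names(features))
      features$treatment <- features$aneurysm_treatment
    else abort_validation("risk features missing column: treatment",
                          field = "treatment")
  }
  check_levels <- function(col, levels) {
    bad <- setdiff(unique(as.character(features[[col]])), levels)
    if (length(bad))
      abort_validation(sprintf("unknown %s level(s): %s", col,
                               paste(bad, collapse = ", ")),
                       field = col)
  }
  check_levels("sex", c("male", "female"))
  check_levels("treatment", c("surgical", "endovascular"))
  check_levels("anticoagulation", c(anticoagulation_levels, "none"))
  check_grade <- function(col, max) {
    v <- features[[col]]
    if (any(is.na(v)) || any(v < 1 | v > max | v != floor(v)))
      abort_validation(sprintf("%s must be an integer in 1..%d", col, max),
                       field = col)
  }
  check_grade("hh_grade", 5)
  check_grade("fisher_grade", 4)
  check_grade("bni_grade", 5)
  if (any(is.na(features$age)) || any(features$age < 0))
    abort_validation("age must be >= 0", field = "age")
  if (any(is.na(features$op_duration_min)) || any(features$op_duration_min <= 0))
    abort_validation("op_duration_min must be > 0", field = "op_duration_min")
  for (i in seq_len(nrow(features))) {
    toks <- split_tokens(features$comorbidities[i])
    if (!length(toks))
      abort_validation("comorbidities must be 'none' or a ';'-joined subset",
                       field = "comorbidities")
    if (length(bad <- setdiff(toks, c(comorbidity_levels, "none"))))
      abort_validation(sprintf("unknown comorbidities level(s): %s",
                               paste(bad, collapse = ", ")),
                       field = "comorbidities")
    if ("none" %in% toks && length(toks) > 1L)
      abort_validation("'none' is mutually exclusive with other comorbidities",
                       field = "comorbidities")
  }
  features
}

#' Encode risk features as a numeric matrix
#'
#' @inheritParams validate_risk_features
#' @param center,scale Optional named vectors of training-set means and
#'   standard deviations for the continuous columns (`age`,
#'   `op_duration_min`); when `NULL` the columns are left on their raw
#'   scale. A fitted model stores and reapplies its own.
#' @return Numeric matrix with `nrow(features)` rows and the
#'   [risk_feature_schema()] columns.
#' @export
encode_features <- function(features, center = NULL, scale = NULL) {
  features <- validate_risk_features(features)
  n <- nrow(features)
  has_com <- function(tok) vapply(features$comorbidities, function(s)
    tok %in% split_tokens(s), logical(1), USE.NAMES = FALSE)
  x <- cbind(
    sex_male = as.numeric(features$sex == "male"),
    age = as.numeric(features$age),
    hh_grade = as.numeric(features$hh_grade),
    fisher_grade = as.numeric(features$fisher_grade),
    bni_grade = as.numeric(features$bni_grade),
    com_hypertension = as.numeric(has_com("hypertension")),
    com_cardiovascular = as.numeric(has_com("cardiovascular")),
    com_pulmonary = as.numeric(has_com("pulmonary")),
    ac_asa = as.numeric(features$anticoagulation == "asa"),
    ac_doac = as.numeric(features$anticoagulation == "doac"),
    ac_antiplatelet = as.numeric(features$anticoagulation == "antiplatelet"),
    ac_combination = as.numeric(features$anticoagulation == "combination"),
    op_duration_min = as.numeric(features$op_duration_min),
    treatment_endovascular = as.numeric(features$treatment == "endovascular")
  )
  stopifnot(identical(colnames(x), risk_feature_schema()))
  if (!is.null(center)) {
    for (nm in names(center)) {
      s <- if (!is.null(scale) && isTRUE(scale[[nm]] > 0)) scale[[nm]] else 1
      x[, nm] <- (x[, nm] - center[[nm]]) / s
    }
  }
  x
}

#' Train the SVM vasospasm-risk model
#'
#' Fits a kernel support vector machine (via [kernlab::ksvm()]) on a
#' labelled cohort and evaluates it with both a holdout split and k-fold
#' cross-validation, each fold refit from scratch. Probabilities come from
#' the SVM's Platt-scaling probability model. The deployed classifier is
#' fit on the full cohort; the holdout and fold accuracies estimate its
#' out-of-sample performance.
#'
#' @param cohort Data frame with the [validate_risk_features()] columns
#'   plus a binary outcome column (0/1 or logical).
#' @param outcome Name of the outcome column (default `"cvs"`).
#' @param kernel Kernel name passed to [kernlab::ksvm()]; default
#'   `"rbfdot"` with the automatic bandwidth heuristic.
#' @param C Soft-margin cost, default 1.
#' @param holdout_frac Fraction of rows held out for the holdout estimate,
#'   default 0.3.
#' @param k_folds Number of cross-validation folds, default 5.
#' @param seed Integer seed making the split, folds, bandwidth heuristic
#'   and Platt scaling reproducible.
#' @return A `costas_risk_model`: the fitted classifier, the encoding
#'   schema and its standardisation statistics, the seed, `holdout_accuracy`,
#'   and `cv_accuracies` (one per fold, with a `cv_mean` attribute).
#' @export
train_risk_model <- function(cohort, outcome = "cvs", kernel = "rbfdot",
                             C = 1, holdout_frac = 0.3, k_folds = 5,
                             seed = 1) {
  if (!outcome %in% names(cohort))
    abort_validation(sprintf("outcome column '%s' not found", outcome),
                     field = outcome)
  y <- as.integer(isTRUE_vec(cohort[[outcome]]))
  n <- nrow(cohort)
  if (n < 20L)
    abort_validation("training cohort must have at least 20 rows")
  if (length(unique(y)) < 2L)
    abort_validation("training cohort must contain both outcome classes")
  feats <- validate_risk_features(cohort)
  yf <- factor(ifelse(y == 1L, "cvs", "no_cvs"), levels = c("no_cvs", "cvs"))

  cont <- c("age", "op_duration_min")
  center <- vapply(cont, function(nm) mean(as.numeric(cohort[[nm]])), numeric(1))
  scale <- vapply(cont, function(nm) stats::sd(as.numeric(cohort[[nm]])), numeric(1))
  scale[scale == 0 | is.na(scale)] <- 1
  x <- encode_features(feats, center = center, scale = scale)

  set.seed(seed)
  fit_svm <- function(xi, yi) kernlab::ksvm(
    xi, yi, type = "C-svc", kernel = kernel, C = C, prob.model = TRUE,
    scaled = FALSE)
  acc <- function(fit, xi, yi) mean(kernlab::predict(fit, xi) == yi)

  hold <- sample.int(n, size = max(1L, round(holdout_frac * n)))
  holdout_accuracy <- NA_real_
  if (length(unique(yf[-hold])) == 2L && length(hold) >= 1L) {
    fit_h <- fit_svm(x[-hold, , drop = FALSE], yf[-hold])
    holdout_accuracy <- acc(fit_h, x[hold, , drop = FALSE], yf[hold])
  }

  fold_id <- sample(rep(seq_len(k_folds), length.out = n))
  cv_accuracies <- vapply(seq_len(k_folds), function(k) {
    tr <- fold_id != k
    if (length(unique(yf[tr])) < 2L) return(NA_real_)
    fit_k <- fit_svm(x[tr, , drop = FALSE], yf[tr])
    acc(fit_k, x[!tr, , drop = FALSE], yf[!tr])
  }, numeric(1))

  fit <- fit_svm(x, yf)
  structure(
    list(fit = fit, schema = risk_feature_schema(),
         center = center, scale = scale,
         kernel = kernel, C = C, seed = seed,
         holdout_accuracy = holdout_accuracy,
         cv_accuracies = cv_accuracies,
         cv_mean = mean(cv_accuracies, na.rm = TRUE),
         n_train = n),
    class = "costas_risk_model")
}

#' @export
print.costas_risk_model <- function(x, ...) {
  cat(sprintf("<costas_risk_model: %s SVM, C = %g, n = %d, seed = %d>\n",
              x$kernel, x$C, x$n_train, x$seed))
  cat(sprintf("  holdout accuracy: %.3f\n", x$holdout_accuracy))
  cat(sprintf("  %d-fold CV accuracy: %.3f (folds: %s)\n",
              length(x$cv_accuracies), x$cv_mean,
              paste(sprintf("%.3f", x$cv_accuracies), collapse = ", ")))
  invisible(x)
}

#' Predict the vasospasm-risk probability
#'
#' @param model A fitted [train_risk_model()] model.
#' @param features Risk features: a data frame (any number of rows) or a
#'   single named list.
#' @return Numeric vector of probabilities in \[0, 1\], one per row,
#'   suitable for [score_ai_risk()].
#' @export
predict_risk <- function(model, features) {
  if (!inherits(model, "costas_risk_model"))
    abort_validation("model must be a fitted costas_risk_model")
  x <- encode_features(features, center = model$center, scale = model$scale)
  if (!identical(colnames(x), model$schema))
    abort_validation("feature schema does not match the fitted model")
  probs <- kernlab::predict(model$fit, x, type = "probabilities")
  p <- as.numeric(probs[, "cvs"])
  pmin(1, pmax(0, p))
}

#' Evaluate a fitted risk model on held-out data
#'
#' @param model A fitted [train_risk_model()] model.
#' @param heldout Labelled feature table disjoint from the training rows.
#' @param outcome Name of the outcome column, default `"cvs"`.
#' @param threshold Probability cut for the positive class, default 0.5.
#' @return A list: `accuracy`, `confusion` (2x2 integer matrix, rows =
#'   truth, columns = prediction), and `n`.
#' @export
evaluate_model <- function(model, heldout, outcome = "cvs", threshold = 0.5) {
  if (!is.data.frame(heldout) || nrow(heldout) == 0L)
    abort_validation("heldout must be a non-empty data frame")
  truth <- as.integer(isTRUE_vec(heldout[[outcome]]))
  p <- predict_risk(model, heldout)
  pred <- as.integer(p >= threshold)
  confusion <- matrix(
    c(sum(truth == 0 & pred == 0), sum(truth == 0 & pred == 1),
      sum(truth == 1 & pred == 0), sum(truth == 1 & pred == 1)),
    nrow = 2, byrow = TRUE,
    dimnames = list(truth = c("no_cvs", "cvs"),
                    predicted = c("no_cvs", "cvs")))
  list(accuracy = mean(pred == truth), confusion = confusion,
       n = length(truth))
}

#' Serialize / restore a fitted risk model
#'
#' The classifier state is written via [serialize()] and base64-encoded
#' into a versioned JSON envelope, so a trained model travels as plain
#' text.
#'
#' @param model A fitted `costas_risk_model`.
#' @param path File path.
#' @return `save_risk_model()` returns `path` invisibly;
#'   `load_risk_model()` returns the model.
#' @export
save_risk_model <- function(model, path) {
  if (!inherits(model, "costas_risk_model"))
    abort_validation("model must be a costas_risk_model")
  payload <- jsonlite::base64_enc(serialize(model, NULL, version = 2))
  jsonlite::write_json(
    list(format = "costas_risk_model", format_version = 1L,
         schema = model$schema, seed = model$seed, payload = payload),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_risk_model
#' @export
load_risk_model <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("model file not found: %s", path))
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "costas_risk_model"))
    abort_io("not a costas risk-model file")
  model <- unserialize(jsonlite::base64_dec(doc$payload))
  if (!inherits(model, "costas_risk_model"))
    abort_io("corrupt risk-model payload")
  model
}
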
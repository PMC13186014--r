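#' Specification of a synthetic SAH cohort
#'
#' Describes a cohort to generate: size and surgical/endovascular split
#' (defaults mirror the 87-patient development cohort, 45 surgical and 42
#' endovascular), baseline prevalence of the symptomatic-vasospasm
#' outcome, and the planted feature-outcome association. Outcomes are
#' drawn from a logistic model: each named effect is a log-odds
#' contribution per standard deviation of its (sample-standardised)
#' feature, and the intercept is calibrated so the cohort's mean outcome
#' probability equals `prevalence`.
#'
#' Default marginals are clinically plausible for an aneurysmal-SAH ICU
#' population (documented in the methods vignette); they are fixed study
#' conditions, not fitting targets.
#'
#' @param n_total Number of patients.
#' @param n_surgical,n_endovascular Treatment split; must sum to `n_total`.
#' @param prevalence Baseline outcome prevalence in (0, 1), default 0.30.
#' @param effects Named numeric vector of planted log-odds effects (names
#'   from `age`, `hh_grade`, `fisher_grade`, `bni_grade`, `smoker`,
#'   `op_duration_min`). Use `effects = c()` for a null cohort.
#' @param ventilated_frac Fraction of patients on mechanical ventilation.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_total = 87L, n_surgical = 45L,
                        n_endovascular = 42L, prevalence = 0.30,
                        effects = default_effects(),
                        ventilated_frac = 0.6, seed = 1L) {
  if (n_surgical + n_endovascular != n_total)
    abort_validation(sprintf(
      "treatment split (%d + %d) must sum to n_total (%d)",
      n_surgical, n_endovascular, n_total))
  if (n_total < 1L) abort_validation("n_total must be >= 1")
  if (!(prevalence > 0 && prevalence < 1))
    abort_validation("prevalence must lie strictly inside (0, 1)")
  effects <- unlist(effects)
  if (length(effects)) {
    ok <- c("age", "hh_grade", "fisher_grade", "bni_grade", "smoker",
            "op_duration_min")
    if (length(bad <- setdiff(names(effects), ok)))
      abort_validation(paste("unknown effect name(s):",
                             paste(bad, collapse = ", ")))
  }
  if (!(ventilated_frac >= 0 && ventilated_frac <= 1))
    abort_validation("ventilated_frac must lie in [0, 1]")
  structure(list(n_total = as.integer(n_total),
                 n_surgical = as.integer(n_surgical),
                 n_endovascular = as.integer(n_endovascular),
                 prevalence = prevalence,
                 effects = effects,
                 ventilated_frac = ventilated_frac,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default planted effect sizes
#'
#' Moderate, clinically oriented log-odds contributions (per SD): worse
#' clinical and radiological grade, older age, smoking and longer
#' operations raise vasospasm risk.
#'
#' @return Named numeric vector.
#' @export
default_effects <- function() {
  c(age = 0.6, hh_grade = 1.0, fisher_grade = 0.8, bni_grade = 0.4,
    smoker = 0.6, op_duration_min = 0.3)
}

#' Load a cohort spec from YAML
#' @param path File path to a YAML mapping of [cohort_spec()] arguments.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cohort spec not found: %s", path))
  args <- yaml::read_yaml(path)
  if (!is.null(args$effects)) args$effects <- unlist(args$effects)
  do.call(cohort_spec, args)
}

#' Generate a synthetic SAH cohort
#'
#' Draws a labelled patient table whose every row passes
#' [validate_record()] and [validate_risk_features()]. The binary
#' symptomatic-vasospasm outcome `cvs` is drawn from the spec's logistic
#' model; the row's true model probability is stored as `ai_risk_prob`
#' (what an oracle risk predictor would output). The Bayes-optimal
#' accuracy implied by the planted signal,
#' `mean(pmax(p, 1 - p))`, is attached as attribute `bayes_accuracy`.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of `spec$n_total` rows with patient-record columns
#'   (`patient_id`, `age`, `smoker`, `iaa_stenosis_pct`, `bmi`, `egfr`,
#'   `pf_ratio`, `peep`, `noradrenaline_mg_per_h`, `weight_kg`,
#'   `ai_risk_prob`), risk-feature columns (`sex`, `hh_grade`,
#'   `fisher_grade`, `bni_grade`, `comorbidities`, `anticoagulation`,
#'   `op_duration_min`, `treatment`), and the outcome `cvs`. Attributes:
#'   `bayes_accuracy`, `seed`.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 7))
#' table(coh$treatment)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_total
  set.seed(spec$seed)

  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    pmin(hi, pmax(lo, x))
  }

  treatment <- sample(c(rep("surgical", spec$n_surgical),
                        rep("endovascular", spec$n_endovascular)))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.6, 0.4))
  age <- floor(rtrunc(n, 55, 12, 18, 90))
  smoker <- stats::runif(n) < 0.40
  hh_grade <- sample(1:5, n, replace = TRUE,
                     prob = c(0.20, 0.30, 0.20, 0.20, 0.10))
  fisher_grade <- sample(1:4, n, replace = TRUE,
                         prob = c(0.10, 0.20, 0.30, 0.40))
  bni_grade <- sample(1:5, n, replace = TRUE,
                      prob = c(0.15, 0.25, 0.30, 0.20, 0.10))

  com <- cbind(hypertension = stats::runif(n) < 0.45,
               cardiovascular = stats::runif(n) < 0.20,
               pulmonary = stats::runif(n) < 0.15)
  comorbidities <- apply(com, 1, function(r) {
    present <- colnames(com)[r]
    if (!length(present)) "none" else paste(present, collapse = ";")
  })
  anticoagulation <- sample(c("asa", "doac", "antiplatelet", "combination",
                              "none"),
                            n, replace = TRUE,
                            prob = c(0.15, 0.08, 0.05, 0.02, 0.70))
  op_duration_min <- round(ifelse(treatment == "surgical",
                                  rtrunc(n, 240, 60, 60, 480),
                                  rtrunc(n, 120, 40, 30, 300)))

  bmi <- round(rtrunc(n, 26, 4, 16, 45), 1)
  weight_kg <- round(rtrunc(n, 78, 15, 45, 130), 1)
  egfr <- round(rtrunc(n, 85, 25, 5, 150))
  iaa_stenosis_pct <- round(ifelse(stats::runif(n) < 0.15,
                                   stats::runif(n, 50, 80),
                                   stats::runif(n, 0, 40)))

  ventilated <- stats::runif(n) < spec$ventilated_frac
  pf_ratio <- ifelse(ventilated, round(rtrunc(n, 250, 80, 60, 480)), NA_real_)
  peep <- ifelse(ventilated, pmin(18, pmax(3, round(stats::rnorm(n, 8, 3)))),
                 NA_real_)
  noradrenaline_mg_per_h <- ifelse(
    stats::runif(n) < 0.5, 0,
    round(pmin(4, stats::rgamma(n, shape = 1.5, scale = 0.6)), 2))

  # planted logistic outcome: standardised effects + calibrated intercept
  feature_pool <- list(age = age, hh_grade = hh_grade,
                       fisher_grade = fisher_grade, bni_grade = bni_grade,
                       smoker = as.numeric(smoker),
                       op_duration_min = op_duration_min)
  eta <- rep(0, n)
  for (nm in names(spec$effects)) {
    v <- feature_pool[[nm]]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) next
    eta <- eta + spec$effects[[nm]] * (v - mean(v)) / s
  }
  intercept <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta)) - spec$prevalence,
    lower = -30, upper = 30)$root
  p <- stats::plogis(intercept + eta)
  cvs <- as.integer(stats::runif(n) < p)

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    sex = sex, age = age, smoker = smoker,
    hh_grade = hh_grade, fisher_grade = fisher_grade, bni_grade = bni_grade,
    comorbidities = comorbidities, anticoagulation = anticoagulation,
    op_duration_min = op_duration_min, treatment = treatment,
    iaa_stenosis_pct = iaa_stenosis_pct, bmi = bmi, weight_kg = weight_kg,
    egfr = egfr, pf_ratio = pf_ratio, peep = peep,
    noradrenaline_mg_per_h = noradrenaline_mg_per_h,
    ai_risk_prob = round(p, 6), cvs = cvs,
    stringsAsFactors = FALSE)
  attr(cohort, "bayes_accuracy") <- mean(pmax(p, 1 - p))
  attr(cohort, "seed") <- spec$seed
  cohort
}

#' Fixture patients at the score extremes
#'
#' `worst_case_patient()` sits in the worst band of every parameter
#' (total 18); `best_case_patient()` sits at every floor (total 0). Both
#' pass [validate_record()].
#'
#' @return A `patient_record`.
#' @export
worst_case_patient <- function() {
  validate_record(list(
    patient_id = "worst-case", age = 70, smoker = TRUE,
    iaa_stenosis_pct = 60, bmi = 32, egfr = 20,
    pf_ratio = 80, peep = 18, noradrenaline_mg_per_h = 2.5,
    ai_risk_prob = 0.9, weight_kg = 80, aneurysm_treatment = "surgical"))
}

#' @rdname worst_case_patient
#' @export
best_case_patient <- function() {
  validate_record(list(
    patient_id = "best-case", age = 40, smoker = FALSE,
    iaa_stenosis_pct = 0, bmi = 22, egfr = 90,
    noradrenaline_mg_per_h = 0, ai_risk_prob = 0.2, weight_kg = 70,
    aneurysm_treatment = "endovascular"))
}
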
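# Shared fixtures and independent oracles.

# Independent re-statement of the printed point bands as plain branches.
# Deliberately not table-driven: this is the oracle the banded lookup is
# checked against.
oracle_points <- function(parameter, v) {
  vapply(v, function(x) {
    switch(parameter,
      age = if (x >= 65) 1L else 0L,
      smoking = if (x >= 1) 1L else 0L,
      iaa = if (x >= 50) 1L else 0L,
      bmi = if (x < 18.5) 0L else if (x < 25) 0L else if (x < 30) 1L else 2L,
      gfr = if (x < 30) 2L else if (x < 45) 1L else 0L,
      pf_ratio = if (x <= 100) 3L else if (x <= 200) 2L
                 else if (x <= 300) 1L else 0L,
      peep = if (x < 5) 0L else if (x < 10) 1L else if (x < 15) 2L else 3L,
      noradrenaline = if (x == 0) 0L else if (x <= 0.5) 1L
                      else if (x < 2) 2L else 3L,
      ai_risk = if (x <= 0.5) 0L else if (x < 0.75) 1L else 2L,
      stop("unknown parameter ", parameter))
  }, integer(1))
}

# One random physically valid patient; ~half are ventilated, AI prob drawn
# uniformly so every band is exercised.
random_raw_patient <- function(id) {
  ventilated <- runif(1) < 0.5
  list(
    patient_id = paste0("R", id),
    age = runif(1, 18, 95),
    smoker = runif(1) < 0.5,
    iaa_stenosis_pct = runif(1, 0, 100),
    bmi = runif(1, 14, 45),
    egfr = runif(1, 2, 140),
    pf_ratio = if (ventilated) runif(1, 50, 450) else NA,
    peep = if (ventilated) runif(1, 0, 24) else NA,
    noradrenaline_mg_per_h = if (runif(1) < 0.3) 0 else runif(1, 0, 4),
    ai_risk_prob = runif(1),
    weight_kg = runif(1, 45, 130)
  )
}

random_records_df <- function(n, seed) {
  withr::with_seed(seed, {
    ventilated <- runif(n) < 0.5
    data.frame(
      patient_id = paste0("R", seq_len(n)),
      age = runif(n, 18, 95),
      smoker = runif(n) < 0.5,
      iaa_stenosis_pct = runif(n, 0, 100),
      bmi = runif(n, 14, 45),
      egfr = runif(n, 2, 140),
      pf_ratio = ifelse(ventilated, runif(n, 50, 450), NA_real_),
      peep = ifelse(ventilated, runif(n, 0, 24), NA_real_),
      noradrenaline_mg_per_h = ifelse(runif(n) < 0.3, 0, runif(n, 0, 4)),
      ai_risk_prob = runif(n),
      weight_kg = runif(n, 45, 130),
      stringsAsFactors = FALSE)
  })
}

# A cleanly separable toy cohort: grade-1 patients never spasm, grade-5
# always do, with the continuous features reinforcing the margin.
separable_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    pos <- rep(c(FALSE, TRUE), length.out = n)
    data.frame(
      sex = sample(c("male", "female"), n, replace = TRUE),
      age = ifelse(pos, runif(n, 70, 85), runif(n, 30, 45)),
      hh_grade = ifelse(pos, 5L, 1L),
      fisher_grade = ifelse(pos, 4L, 1L),
      bni_grade = ifelse(pos, 5L, 1L),
      comorbidities = "none",
      anticoagulation = "none",
      op_duration_min = ifelse(pos, runif(n, 240, 300), runif(n, 60, 120)),
      treatment = sample(c("surgical", "endovascular"), n, replace = TRUE),
      cvs = as.integer(pos),
      stringsAsFactors = FALSE)
  })
}

balanced_spec <- function(n, seed, ...) {
  cohort_spec(n_total = n, n_surgical = ceiling(n / 2),
              n_endovascular = floor(n / 2), seed = seed, ...)
}
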
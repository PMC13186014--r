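---
title: "The COSTAS scale: methods, numerical choices, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The COSTAS scale: methods, numerical choices, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costas)
```

## The model

COSTAS is a deterministic, threshold-based point scale. Nine clinical
parameters — age, cigarette smoking, intracranial arterial atherosclerosis
(IAA), body-mass index, estimated glomerular filtration rate, the
PaO₂/FiO₂ ratio, PEEP, the continuous noradrenaline dose, and a
machine-learned vasospasm-risk probability — are each mapped onto a band
of 0–3 points, and the total is the unweighted sum, 0–18. The scale makes
no outcome claim by itself: it condenses the clinical state of an SAH
patient with suspected symptomatic vasospasm into a transparent number
supporting the decision for or against intra-arterial spasmolysis. No
cutoff on the total is defined, deliberately: the package reports the
score and its per-parameter breakdown, nothing more.

The binary parameters reward established vascular risk (age ≥65 years,
active smoking, ≥50% stenosis of an intracranial vessel on angiography,
TCD or intraoperative inspection). The graded parameters reuse
field-standard classifications — WHO BMI classes, KDOQI renal-risk
classes, Berlin ARDS severity for the P/F ratio — so the bands need no
local recalibration to be understood. Noradrenaline requirement enters in
mg/h, the institutional standardisation unit, as a surrogate of
hemodynamic instability. The AI parameter clusters a predicted vasospasm
probability into three bands (≤50%, 51–74%, ≥75%).

## Band edges and gap closing

The printed bands are finite decimal labels over continuous quantities,
so the shipped table (`costas_table()`) interprets them as half-open real
intervals and closes the typographical gaps explicitly:

* BMI "25–29.9" becomes [25, 30); "18.5–24.9" becomes [18.5, 25).
* A P/F ratio of exactly 100 mmHg is unassigned between "less than 100"
  and "101 to 200"; it scores 3 — ties break toward severity.
* Noradrenaline 0.5–0.6 and 1.9–2 mg/h close onto the higher band:
  (0.5, 2) scores 2, [2, ∞) scores 3.
* Values better than the best printed band score 0; eGFR ≥60 mL/min and
  BMI <18.5 additionally carry flags (`above_kdoqi_bands`,
  `underweight_unspecified`) because the scale simply does not speak
  there. PEEP above the printed 20 cm H₂O ceiling keeps 3 points with
  `peep_above_band`.
* AI probabilities: [0, 0.50] → 0, (0.50, 0.75) → 1, [0.75, 1] → 2, so
  every probability maps to exactly one band.
* A patient who is not mechanically ventilated scores 0 on both P/F and
  PEEP: without a ventilator there is no ventilation burden to grade.

The table is data, not code: `write_scoring_table()` /
`read_scoring_table()` round-trip it through YAML, so a multicenter
revision is a config change. `validate_scoring_table()` enforces
non-overlap, gap-freeness, full domain coverage and the 18-point maximum
on any table it loads.

## Screening rules

Suspected CVS on transcranial Doppler fires when the mean flow velocity
exceeds 190 cm/s (strict: exactly 190 does not trigger) or has risen by
at least 50% relative to the previous same-vessel measurement (inclusive
at exactly 50%). A previous velocity of 0 makes the relative ratio
undefined: the absolute rule is evaluated first, and only if it does not
decide is the zero baseline a validation error. DCI-attributable
deterioration requires a new focal deficit (hemiparesis, aphasia,
apraxia, hemianopsia, neglect) or a GCS drop of ≥2 points on the total or
any single component, sustained ≥1 hour, and not attributable to another
cause — attribution is an adjudicated input flag (CT/MRI/lab exclusion),
never computed. GCS components are recorded with motor on either side;
the conventional 3–15 total uses the better motor side, while each side's
drop counts separately as a component criterion. MAP targets of the
induced-hypertension protocol (80–90 mmHg, >100 mmHg if spasm persists)
are exported as constants (`map_targets()`) for reporting; no rule gates
on them.

## Dosing arithmetic

The standard infusion dilutes a 5 mg / 5 mL noradrenaline vial with 45 mL
of 0.9% saline to 50 mL — 0.1 mg/mL — so pump rate in mL/h is dose/0.1.
`convert_dose()` bridges mg/h to the weight-based literature unit:
µg/kg/min = mg/h × 1000 / 60 / kg. The literature shock bands (mild
<0.1, moderate 0.1–0.3, severe 0.3–0.5, refractory >0.5 µg/kg/min) are
informational only — the cutoffs are empirical and without consensus, and
the COSTAS points use the institutional mg/h bands. Band boundaries are
assigned to the higher-severity side, consistent with the "<0.1" lower
band.

## The risk model

The AI parameter is a kernel SVM (`kernlab::ksvm`) over sex, age,
Hunt & Hess (1–5), Fisher (1–4) and BNI (1–5) grades, comorbidities
(arterial hypertension, cardiovascular, pulmonary, or none),
anticoagulation (ASA, DOAC, antiplatelet, combination, or none),
operation/intervention duration, and treatment modality. Categorical
fields are one-hot encoded against the "none" reference, ordinal grades
stay integer, and age and operation duration are standardised with
training-set statistics stored in the fitted model. Defaults — an RBF
kernel with the automatic bandwidth heuristic, C = 1, a 30% holdout, and
5-fold cross-validation with every fold refit from scratch — are package
choices, exposed as arguments, since the classification method is fixed
but its hyperparameters are not. Probabilities come from the SVM's
standard Platt-scaling probability model. All stochastic steps (split,
folds, bandwidth estimation, Platt fitting) run under one integer seed,
so identical inputs give identical evaluations. The deployed classifier
is refit on the full cohort; the holdout and fold accuracies estimate its
out-of-sample performance.

No real patient data ship with the package, so all accuracy statements
are about synthetic cohorts; the development cohort's reported accuracy
range is a property of data this package does not have and is not a
validation target here.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of an 87-patient aneurysmal-SAH
cohort (45 surgical, 42 endovascular by default) for testing and for
training the risk model. Marginals are fixed, clinically plausible
choices for a neuro-ICU SAH population: 60% female; age ≈ N(55, 12²)
truncated to 18–90; 40% smokers; Hunt & Hess weighted toward grades 2–4
and Fisher toward 3–4; 45%/20%/15% hypertension/cardiovascular/pulmonary
comorbidity; 70% without anticoagulation; operation durations around
240 min (surgical) and 120 min (endovascular); BMI ≈ N(26, 4²);
eGFR ≈ N(85, 25²); 15% with ≥50% intracranial stenosis; 60% ventilated
with P/F ≈ N(250, 80²) and PEEP ≈ N(8, 3²); half without noradrenaline,
the rest gamma-distributed below 4 mg/h.

The binary symptomatic-vasospasm outcome is planted through a logistic
model: standardised age, Hunt & Hess, Fisher, BNI, smoking and operation
duration contribute log-odds of 0.6, 1.0, 0.8, 0.4, 0.6 and 0.3 per SD —
a moderate, clinically oriented signal — and the intercept is calibrated
by root finding so the cohort's mean outcome probability equals the
specified prevalence (default 0.30, a typical symptomatic-vasospasm
rate). The per-row true probability is stored as `ai_risk_prob` (the
output of an oracle predictor), and the implied Bayes-optimal accuracy,
`mean(pmax(p, 1 - p))`, is attached as an attribute so model evaluations
have a ceiling to compare against.

What the generator does not emulate: the covariance structure of real SAH
data (features are drawn independently), measurement error, repeated
measurements and time courses, missingness beyond the ventilation fields,
or any attempt to match the development cohort's accuracy range. Passing
tests therefore demonstrate that the scale and model machinery are
correct and stable under known conditions — not that the planted effect
sizes are clinically true.

## Validation design and problem sizes

The test suite checks, at sizes chosen to keep the whole run in minutes
on one CPU: the per-parameter maxima (1,1,1,2,2,3,3,3,2) summing to 18
and the fixture patients at 18 and 0; every printed band midpoint and
edge; 10,000 randomized valid records staying within 0–3 per parameter
and 0–18 in total; agreement of the table-driven band lookup with an
independent brute-force re-statement of the printed rules on a dense grid
of roughly 10⁵ points; monotonicity of every scorer and of the total
under single-parameter worsening; dose-conversion round trips to 1e-9; a
constructed truth table for the screening rules; and, for the risk model,
seed-reproducibility plus test accuracy within 5 percentage points of the
planted Bayes accuracy when trained on a 1,000-patient synthetic cohort
and evaluated on an independent 2,000-patient one. The evaluation cohort
is generated separately rather than split from the training cohort so
that binomial noise in a small holdout does not masquerade as model
error.

## Known limitations

* Smoking is a single boolean; the underlying clinical definition
  (current vs former, pack-years) is not specified by the scale and the
  record does not try to resolve it.
* IAA is assessed once per patient, not per spastic territory.
* The scale's weights are prototype choices of its authors; this package
  reproduces the scale and its evaluation machinery, it does not validate
  the weights against outcomes.
* The risk model trained on synthetic cohorts has no clinical validity;
  it exists so the full pipeline — features to probability to AI band to
  total — is executable and testable end to end.
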
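# costas

Clinically oriented scoring for intra-arterial spasmolysis triage after
aneurysmal subarachnoid hemorrhage (SAH).

Symptomatic cerebral vasospasm (CVS) is among the most dangerous sequelae
of a ruptured cerebral aneurysm. Intra-arterial spasmolysis (catheter
infusion of nimodipine into spastic vessels) can rescue such patients, but
it is invasive and only a subgroup benefits. The COSTAS scale addresses
patient selection: it condenses nine routinely available quantities into a
single 0–18 point total describing how much a patient stands to gain — and
how much burden they already carry — at the moment the decision is made.
It is aimed at neuro-ICU and neurointerventional teams and at methods
researchers evaluating threshold-based triage scales.

## The scale

Each parameter maps onto a point band; the total is the plain sum
(maximum 18):

| Parameter | Bands → points |
|---|---|
| Age | ≥65 y → 1 |
| Cigarette smoking | yes → 1 |
| Intracranial arterial atherosclerosis | stenosis ≥50% → 1 |
| BMI (kg/m²) | 18.5–24.9 → 0, 25–29.9 → 1, ≥30 → 2 |
| eGFR (mL/min, KDOQI) | 45–59 → 0, 30–45 → 1, <30 → 2 |
| PaO₂/FiO₂ (mmHg, Berlin) | 201–300 → 1, 101–200 → 2, ≤100 → 3 |
| PEEP (cm H₂O) | 5–9 → 1, 10–14 → 2, ≥15 → 3 |
| Noradrenaline (mg/h) | 0 → 0, ≤0.5 → 1, 0.5–2 → 2, ≥2 → 3 |
| AI vasospasm-risk probability | ≤50% → 0, 51–74% → 1, ≥75% → 2 |

Non-ventilated patients score 0 on both ventilation parameters. Band
edges, gap-closing choices and transparency flags are documented in
`?costas_table` and the methods vignette. The AI parameter is fed by a
kernel support-vector-machine risk model (features: sex, age, Hunt & Hess,
Fisher and BNI grades, comorbidities, anticoagulation, operation duration,
treatment modality) evaluated by holdout and k-fold cross-validation.
Around the scale sit the screening rules that trigger scoring — suspected
CVS on transcranial Doppler (>190 cm/s or a ≥50% velocity rise) and
DCI-attributable deterioration (new focal deficit or GCS drop ≥2 for
≥1 h, no other cause) — and noradrenaline dosing arithmetic (0.1 mg/mL
standard infusion, mg/h ↔ µg/kg/min conversion, literature shock bands).

## Worked example

```r
library(costas)
rec <- validate_record(list(
  patient_id = "P01", age = 70, smoker = TRUE, iaa_stenosis_pct = 0,
  bmi = 28, egfr = 50, pf_ratio = 250, peep = 8,
  noradrenaline_mg_per_h = 1.0, ai_risk_prob = 0.6, weight_kg = 75))
total_score(rec)
#> COSTAS score for P01 (table costas-1.0)
#> age            1 point  (>=65 y)
#> smoking        1 point  (smoker)
#> iaa            0 points  (stenosis <50%)
#> bmi            1 point  (overweight)
#> gfr            0 points  (low risk)
#> pf_ratio       1 point  (mild)
#> peep           1 point  (mild)
#> noradrenaline  2 points  (moderate risk)
#> ai_risk        1 point  (moderate risk)
#> TOTAL: 8 / 18
```

This patient accumulates 8 of 18 points: geriatric age, smoking, moderate
overweight, mild ventilation burden on both parameters, a moderate
noradrenaline requirement (1.0 mg/h — at the standard 0.1 mg/mL syringe
that is a 10 mL/h pump rate, or 0.222 µg/kg/min at 75 kg, "moderate" on
the literature shock bands), and a moderate AI-predicted vasospasm risk.
The scale defines no treat/no-treat cutoff; the total and its per-parameter
breakdown are the output.

Training and using the risk model on a synthetic cohort:

```r
coh <- generate_cohort(cohort_spec(n_total = 500, n_surgical = 250,
                                   n_endovascular = 250, seed = 1))
m <- train_risk_model(coh, seed = 1)
predict_risk(m, coh[1, ])       # probability in [0, 1], feeds score_ai_risk()
```

A command-line front end ships in `inst/cli/costas.R`
(`Rscript inst/cli/costas.R score patients.csv`, plus `screen`, `dose`,
`cohort`, `train`, `predict`, `evaluate`).

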
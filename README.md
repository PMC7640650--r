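# akicds — clinical decision support engine for hospital-acquired AKI

Acute kidney injury (AKI) is a frequent complication in hospitalized
patients and often goes unrecognized until late. `akicds` implements, as a
testable engine decoupled from any EMR, the logic of an electronic
decision-support suite for AKI on general medical and surgical units:

- **Stage alerts.** Every in-hospital serum creatinine result (the *index*
  value, SCr in µmol/L) is compared with a baseline chosen
  NHS-England-style: the lowest creatinine of the prior 7 days if any
  exist, otherwise the median of all values from the preceding year.
  KDIGO creatinine criteria then assign a stage:
  stage 1 if SCr ≥ 1.5 × baseline or SCr rose ≥ 26.5 µmol/L within 48 h;
  stage 2 if SCr ≥ 2.0 × baseline;
  stage 3 if SCr ≥ 3.0 × baseline or SCr ≥ 353.6 µmol/L.
  (Urine-output criteria are deliberately out of scope; ward urine-output
  records are too unreliable to alert on.)
- **Alert lifecycle.** One alert when any stage is first met; further
  alerts within an episode only on progression to a higher stage;
  recovery (a result assessed at stage 0) closes the episode; a later
  qualifying result opens a new episode and alerts again. Alerts can be
  acknowledged (idempotently) but are never deleted from history.
- **Adverse medication warnings.** An interruptive, overridable warning
  when a drug that may reduce kidney function (diuretics, nephrotoxic
  antibiotics, ACE inhibitors / ARBs, NSAIDs — a formulary-driven list) is
  ordered within 48 h of AKI onset during an open episode.
- **Clinical summary dashboard.** A pure aggregation at a point in time:
  alert history, creatinine/urea/electrolyte trends, may-worsen-AKI and
  renally-cleared medication panels, urine output and fluid balance per
  interval, IV therapies, vitals, infection markers, visit history.
- **Order set.** Volume-status-branched recommendations: IV fluid boluses
  (with mandatory monitoring safety parameters) for hypovolemic patients,
  maintenance fluids for euvolemic, diuretics for hypervolemic, plus
  ultrasound guidance, per-drug hold/review items and nephrology-referral
  criteria.
- **Silent mode.** Batch evaluation of a whole cohort with display side
  effects suppressed, producing audit frequency tables (counts and
  one-decimal percentages by stage, medication class and unit type).
- **Synthetic cohorts.** A seeded generator plants AKI episodes with known
  onset, stage and recovery into realistic creatinine streams, so every
  component is testable with no patient data.

Intended users are health-informatics teams and researchers who want to
audit, re-parameterize or stress-test AKI e-alerting logic outside a
production EMR.

## Worked example

One surgical patient: creatinine 82 → 84 → 150 → 172 → 90 µmol/L on
consecutive mornings, with an NSAID ordered the evening of day 3.

```r
library(akicds)
labs <- data.frame(
  patient_id = "P0001", encounter_id = "E0001", analyte = "creatinine",
  value = c(82, 84, 150, 172, 90),
  collected_at = as.POSIXct("2024-03-01 08:00", tz = "UTC") + 0:4 * 86400,
  setting = "hospital")
meds <- data.frame(
  patient_id = "P0001", encounter_id = "E0001", drug_name = "naproxen",
  ordered_at = as.POSIXct("2024-03-03 20:00", tz = "UTC"),
  discontinued_at = as.POSIXct(NA))
enc <- data.frame(
  patient_id = "P0001", encounter_id = "E0001",
  admit_time = as.POSIXct("2024-03-01 06:00", tz = "UTC"),
  discharge_time = as.POSIXct(NA), unit_type = "surgical", unit_name = "gs-1")

res <- run_silent(aki_cohort(labs = labs, meds = meds, encounters = enc))
res$alerts[, c("alert_id", "stage", "raised_at", "ratio", "baseline_value")]
#>      alert_id stage           raised_at    ratio baseline_value
#> 1 P0001-e1-s1     1 2024-03-03 08:00:00 1.829268             82
#> 2 P0001-e1-s2     2 2024-03-04 08:00:00 2.097561             82
res$warnings[, c("drug_name", "drug_class", "aki_stage_at_order")]
#>   drug_name drug_class aki_stage_at_order
#> 1  naproxen      nsaid                  1
```

Day 3's 150 µmol/L is 1.83 × the 7-day-lowest baseline of 82 → a stage 1
alert at the result's collection time. Day 4's 172 µmol/L crosses 2 ×
baseline → one progression alert at stage 2. Day 5's 90 µmol/L is below
every criterion → recovery closes the episode (no alert). The NSAID was
ordered 36 h after onset, inside the 48-h window of the open episode, so
it draws one interruptive warning attributed to stage 1 — the highest
stage alerted *at the order time*. `print(res$report)` renders the audit
table with `N (P)` cells, e.g. `Stage 1 AKI alerts  1 (50.0)`.

A shell entry point wrapping the same functions ships in
`inst/scripts/akicds.R`:

```sh
Rscript inst/scripts/akicds.R simulate --seed 1 --n 100 --out scratch/demo
Rscript inst/scripts/akicds.R silent-report --events scratch/demo/events.csv --out scratch/demo
```

## Configuration files

Staging thresholds, the medication formulary and the order-set template
are JSON (schemas in `inst/extdata/*.schema.json`). The shipped formulary
(`inst/extdata/default_formulary.json`) is a representative per-class
agent list, not a canonical institutional formulary — deployments should
substitute their own. See `vignette("aki-cds-methods")` for the detection
rules, generator model, numerical choices and known limitations.
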
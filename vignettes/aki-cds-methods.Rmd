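---
title: "Detection rules, generator model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection rules, generator model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akicds)
```

`akicds` is a rule-based engine, not a statistical model: its value lies
in the exact operational semantics of AKI detection, the alert lifecycle,
the medication-warning rule, and the audit aggregation. This vignette
records those semantics, the reasoning behind the choices that were
genuinely open, the synthetic-data model used to exercise them, and what
the passing test suite does and does not establish.

## Baseline selection

For an index creatinine collected at time $t$, the baseline is chosen in
two tiers over the patient's prior creatinine results (hospital and
community alike; the index result itself is never eligible):

1. **Short window** — if any result falls in the open interval
   $(t - 7\,\mathrm{d},\, t)$, the baseline is the *lowest* such value.
2. **Long window** — otherwise, if any result falls in
   $(t - 365\,\mathrm{d},\, t - 7\,\mathrm{d}]$, the baseline is their
   median (even counts: arithmetic mean of the middle pair).
3. Otherwise the baseline is *unavailable*; only the absolute criteria
   can then stage the result.

Choices worth recording:

- *Lowest vs most recent in the short window.* The NHS-England-style
  algorithm family uses the lowest recent value, which makes the ratio
  conservative against same-admission creatinine drift; we default to
  `"lowest"` and expose `baseline_short_method = "most_recent"` for
  sites that prefer the alternative reading.
- *Half-open windows.* $(t-W, t)$ excludes both the index result and
  results exactly $W$ old from the short window (a result exactly 7 days
  old belongs to the long window). This prevents self-referential
  baselines and gives every result an unambiguous tier.
- *Recomputation.* The baseline is recomputed at every result rather than
  frozen at episode onset. During a long episode the short window can
  fill with elevated values, which deflates the ratio — a real property
  of rolling-window baselines that users should be aware of (see
  *Limitations*).

## Staging

With ratio $r = \mathrm{SCr}/\mathrm{baseline}$ and 48-h rise
$\Delta_{48}$ = index value minus the minimum creatinine in
$(t - 48\,\mathrm{h},\, t)$:

| stage | criterion |
|---|---|
| 3 | $r \ge 3.0$ **or** SCr $\ge 353.6$ µmol/L |
| 2 | else $r \ge 2.0$ |
| 1 | else $r \ge 1.5$ **or** $\Delta_{48} \ge 26.5$ µmol/L |
| 0 | otherwise |

All five constants are `staging_config()` defaults, taken from the KDIGO
creatinine criteria expressed in µmol/L, and every one is overridable;
thresholds are compared with `>=` (meeting a threshold qualifies).
When the baseline is unavailable the ratio criteria are skipped, not
failed — the absolute criteria still apply. Creatinine is µmol/L
throughout; the reader converts mg/dL by ×88.4 when told to.

## Alert lifecycle

Per patient, hospital creatinine results are evaluated in arrival order
(community results feed baselines but are never index values):

- First result assessed at stage ≥ 1 opens an episode and raises an
  alert; the alert's `raised_at` equals the result's collection time.
- Within an episode a new alert is raised only when the assessed stage
  exceeds the highest stage already alerted (progression). De-escalation
  raises nothing and does not lower that high-water mark.
- A result assessed at stage 0 under the *full* rule (ratio and 48-h
  criteria all unmet) closes the episode; the next qualifying result
  opens episode $k+1$ and alerts again.
- Acknowledgment flips display status only, idempotently; alerts are
  permanently retained, and the dashboard shows acknowledged alerts.

This yields two invariants the property tests assert on generated
cohorts: at most one alert per (patient, episode, stage), and strictly
increasing alerted stages within an episode.

## Medication warnings

A warning is raised at order entry iff the patient is in an open episode,
the drug's formulary entry has `may_cause_aki = TRUE`, and the order time
lies in the closed interval $[\text{onset},\, \text{onset} + 48\,\mathrm{h}]$.
"Within 48 h" does not specify its boundaries; we include both ends and
document it, since an order placed exactly at the window edge is the case
clinicians would expect to be caught. Whether warnings should also fire
later in a long-running episode is genuinely unsettled; the literal
48-h-from-onset rule is the default and
`warn_any_time_in_episode = TRUE` switches to the episode-long reading.
The warning's attributed stage is the highest stage alerted in that
episode *at or before* the order time — the only stage attribution the
audit tables support. Warnings never block anything; they are recorded
with an `overridden` flag for auditability.

The shipped formulary is a representative per-class agent list (loop and
thiazide diuretics; aminoglycosides and vancomycin; common ACEi/ARBs;
common NSAIDs; a few renally-cleared-only agents). It is configuration,
not clinical authority, and is expected to be replaced per deployment.

## Dashboard and order set

The dashboard is a pure function of the events at or before `as_of`:
appending later events can never change an earlier dashboard (tested).
Fluid and urine summaries use half-open bins $[s, s+w)$ of width 8 h by
default — nursing-shift granularity — anchored at admission, so that
per-bin balances sum exactly to the whole-window balance (additivity is
tested). A drug flagged both `may_cause_aki` and `renally_cleared`
appears in both medication panels; both facts are clinically relevant.
The electrolyte panel defaults to sodium, potassium and bicarbonate.

The order-set engine owns only structure: exactly one fluid strategy per
volume status (bolus / maintenance / diuresis), bolus ⇒ non-empty
monitoring items, one review item per active at-risk drug, ultrasound
guidance on suspected obstruction, pharmacy consult on request,
nephrology-referral criteria always listed. All wording lives in an
editable JSON template because order-set text is an institutional
document; doses and rates are prescriber placeholders by design.

## Audit report arithmetic

Percentages are `100 * count / total` rounded to one decimal, half away
from zero (R's `round()` rounds half to even, which audit tables do not).
Denominators are the relevant totals (total alerts or total warnings) for
every row, including the per-class medication rows. Each distinct
medication class counts at most once per alert. Zero-total partitions
render their percent as an em dash rather than dividing by zero. These
rules are exposed via `cohort_report_from_counts()` so that externally
tabulated counts can be pushed through the identical arithmetic.

## Synthetic cohort model

`generate_cohort()` plants ground truth rather than sampling physiology.
Each patient has a personal baseline $b \sim \mathrm{lognormal}$
(median 80 µmol/L, σ = 0.25 by default) and a creatinine series sampled
roughly daily over a 4–14 day stay. An episode, planted with probability
`aki_incidence`, multiplies the series by a ratio drawn from the planted
stage's band, shrunk 5% inside the band edges
(stage 1: $[1.575, 1.9]$; stage 2: $[2.1, 2.85]$;
stage 3: $[3.15, 3.75]$), then returns it to baseline — a flat → step →
decay trajectory, the simplest shape that exercises every detection rule.
Multiplicative lognormal noise with configurable CV (default 2%,
ordinary analytic variation) is applied last. Two guards make planted
truth exact under zero noise: the elevated phase is capped at 5 days so
the 7-day lowest-value baseline window always retains a pre-onset value,
and baselines of sub-stage-3 episodes are capped so the planted peak
cannot cross the 353.6 µmol/L absolute threshold.

Defaults emulate the population of a multi-unit 30-day silent audit:
450 patients admitted over 30 days, 18% episode incidence, planted stage
mix (0.667, 0.173, 0.160), 20% surgical encounters, and per-class
medication exposure (diuretic 0.20, antibiotic 0.10, ACEi/ARB 0.12,
NSAID 0.08) chosen so a bit under half of alerts carry an active at-risk
medication — the same order of magnitude as a real silent phase, chosen
once and not tuned further. `progression_probability` defaults to 0 so
the default alert-stage mix equals the planted mix; progression is
exercised explicitly by fixtures and property tests.

What the generator does **not** emulate: GFR kinetics or drug
pharmacokinetics, seasonal or unit-level casemix, correlated ordering
behavior, missing or duplicated lab draws, and transfer between units.
Passing tests therefore demonstrate that the engine implements its stated
rules exactly and recovers truth planted under those rules — not that the
rules achieve any particular sensitivity on real EMR data.

## Numerical and representational choices

- Timestamps are ISO-8601 on disk, POSIXct UTC in memory, whole-second
  resolution; same-timestamp events keep input order (stable sort), so
  replay is deterministic.
- Numeric values serialize with `%.17g`, so streams round-trip doubles
  exactly through both CSV and JSON-lines.
- Threshold comparisons are exact `>=` with no epsilon: config values are
  round decimals and inputs are data, so tolerance windows would only
  blur the contract.
- Degenerate inputs are defined, not errors: empty files read as empty
  cohorts, patients without creatinine produce no output, zero-total
  report partitions render blank percents, and an unavailable baseline
  still allows absolute-criterion staging.
- The generator restores the caller's RNG state; identical seeds give
  byte-identical cohorts.

## Test-suite problem sizes

The oracle-equivalence suite replays 1,000 randomized patients against a
brute-force whole-history oracle and enumerates all (order, episode)
pairs for the warning engine; parameter recovery uses 300-patient planted
cohorts (noiseless, then 2% CV); stage-mix recovery uses 600 planted
episodes, where the 95% binomial half-width of every stage proportion is
under 5 percentage points. These sizes were chosen to make the checks
statistically meaningful while keeping the whole suite comfortably under
a minute on a laptop.

## Limitations

- Urine-output and renal-replacement-therapy criteria are out of scope by
  design; stage 3 via dialysis initiation will not alert.
- The rolling 7-day lowest baseline deflates ratios during episodes
  longer than a week, which can register as premature "recovery"; this is
  a property of the baseline family itself, surfaced here rather than
  patched.
- Stage attribution of warnings depends on alerts already raised; an
  order placed between onset and the first progression alert is
  attributed the lower stage.
- The fixture scenario matrix is original to this package; it covers
  every behavior the engine implements, but it is not a transcription of
  any institution's validation suite.
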
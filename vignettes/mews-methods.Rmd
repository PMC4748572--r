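---
title: "Methods: scoring, threshold audit, callout simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, threshold audit, callout simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mewsr)
```

## The score

The Modified Early Warning Score implemented here sums six parameters,
each contributing 0–3 points: systolic blood pressure, heart rate,
respiratory rate, temperature, the AVPU consciousness scale, and a
binary "any concern about the patient's condition" item scored 1. The
maximum total under the default table is 15. Urine output and
oxygen-related items, present in some MEWS/NEWS variants, are
deliberately absent: this rubric is designed to be computable for
*every* inpatient from routine vital-sign charting.

**Band alignment.** Published flat renderings of such rubrics do not
always make the band-to-points assignment unambiguous at the extremes
(does HR ≤ 40 score 2 or 3?). The default table uses the alignment
consistent with the Subbe-style MEWS for acute medical admissions
(HR ≤ 40 → 2, RR ≤ 8 → 2, SBP ≥ 200 → 2, temperature extremes → 2);
since the whole table is configuration (`load_score_table()`, YAML or
JSON), any other institutional reading is a one-line override, and the
package makes no claim that this alignment is the only defensible one.

**Interval convention.** Printed bands are inclusive ranges at the
parameter's measurement granularity (0.1 °C for temperature, integers
elsewhere). Inputs are rounded half-up to that granularity before
lookup, which makes the printed bands exhaustive (35.04 °C → 35.0 →
2 points; 35.05 °C → 35.1 → 0 points). Band partition is verified by a
dense-grid property test over each parameter's full physiological
range.

**Missing data.** The default policy scores a missing parameter as 0
and records it in `missing_parameters`, so totals are conservative
(never inflated) and auditable; a `strict` policy that refuses missing
data is selectable. An observation with all six parameters missing is
always an error. The source protocol never describes missing data, so
this is a package decision.

**Daily reduction.** Scoring happens one or more times a day; the
patient's score for a day is the maximum over that calendar day (local
date of the timestamp), and ties are broken by the earliest
observation so reports are deterministic.

## The warning-zone audit

`stratify()` tabulates patients and arrests by maximum score, with
exact Clopper–Pearson 95% intervals attached as reporting aids (the
original audit reports none). `select_wz()` scans candidate thresholds
`t` in increasing order and accepts the smallest `t` such that *every*
stratum at or above `t` has a significantly higher rate than the
stratum immediately below `t` — the generalization of comparing scores
7, 8 and ≥ 9 against score 6.

**Which test.** Both the uncorrected Pearson chi-squared test and
Fisher's exact hypergeometric test are implemented, and they disagree
on exactly one comparison in the reference audit: 2/114 (score 8)
versus 1/556 (score 6) gives p ≈ 0.022 by uncorrected chi-squared but
p ≈ 0.077 one-sided exact. Only the uncorrected chi-squared reproduces
the "all strata ≥ 7 significant" pattern, so it is the default for
threshold selection, with the exact test available for audit — the
package treats this as a documented property of the data, not a
recommendation that asymptotic tests be preferred at these event
counts. No multiplicity correction is applied across the stratum
tests, matching the audit being reproduced; all raw p-values are
recorded in the decision object. Empty strata (a pooled top bin with
no patients) carry no test and are dropped from the scan.

**Numerical note.** The Pearson statistic is computed in doubles: the
cross-product term `ad − bc` overflows 32-bit integers already at
period-scale tables (~15,000 admissions), which a property test
(chi-squared ≡ squared two-proportion z statistic) caught during
development.

## Incidence analysis

Rates are denominated per 1000 *admission episodes* (whether
"admissions" means episodes or unique patients is unstated in the
source; episodes are the auditable unit). An admission and its events
belong to the month of the admission date. Monthly control limits are
the arithmetic mean ± 1 sample SD of the monthly rates, computed per
period; the mean of monthly rates equals the pooled rate only when
monthly denominators are equal, and a test documents the inequality.
Report rounding (half-up; 2 decimals for per-1000 rates and stratum
percentages, 1 decimal for background percentages) happens at the
writer layer; internal values keep full precision.

## The synthetic world

No microdata exist for this system, so `generate_cohort()` states a
world and every stochastic claim in the test suite is a claim about
that world:

* **Scale.** 17,961 admissions over 18 months (~998/month), the
  post-introduction period scale; the pre-introduction fixture uses
  15,170.
* **Length of stay.** Geometric with mean 10 days (minimum 1): a
  ~331-bed hospital at ~998 admissions/month implies a mean LOS of
  about 331 × 30/998 ≈ 10 days.
* **Severity.** Each admission draws a *maximum-score stratum* from
  weights proportional to the audit counts 556/289/114/56 for strata
  6/7/8/≥9, with the sub-6 mass set so that the warning-zone fraction
  is exactly 920/17,961 — making the monthly mean WZ census 51.1 by
  construction. The daily path holds a low score, rises to the maximum
  for a geometric excursion (persistence 0.6, mean 2.5 days at peak),
  and returns; this "chain conditioned on its maximum" replaces an
  unconditional Markov chain because it is exactly calibratable to the
  stratum distribution.
* **Hazards.** Per-admission IHCA probabilities are the audit rates
  (1/556, 4/289, 2/114, 2/56), attached to the admission's maximum
  stratum and converted to a per-day hazard `h = 1 − (1 − p)^{1/d}`
  over its `d` days at that stratum, so the per-admission probability
  is reproduced exactly without intervention. Death occurs at
  discharge with probability 636/17,961, independent of the score — a
  simplification; real arrest and death are correlated.
* **Vitals.** `sample_vitals_for_score()` inverts the rubric: a
  uniform draw over all per-parameter point decompositions of the
  target total, then a uniform grid draw within a band carrying those
  points. Rescoring reproduces the target exactly (round-trip property,
  all targets × 1000 draws). The generator emulates *band-consistent*
  vitals only — no autocorrelation, circadian structure, or
  inter-parameter physiology — so a green test establishes contract
  correctness of scoring and plumbing, not clinical realism.
* **Other backgrounds.** Age normal 59.3 ± 28 truncated at 0, 54.4%
  male, published top-5 diagnosis frequencies, DNR fraction 0.05 (not
  reported by the source; a typical acute-care prevalence, chosen once).

## The callout simulator

`step_callout()` is the escalation pathway as a state machine: below
threshold → keep monitoring; at/above threshold → DNR patients have
the pathway terminated, others get the full one-time alert cascade
(ward nurses alert physician and ICU nurses, treatment starts); an
alerted patient who continues to deteriorate is transferred to ICU
(per-day probability `deterioration_escalation_prob`, a qualitative
knob with no claimed fidelity).

`simulate_study()` applies a multiplicative hazard reduction θ from
the first alert day onward — the minimal mechanism that produces a
rate reduction confined to warning-zone patients. θ is a free
parameter (default 0.46, the observed before/after ratio), not an
observed quantity. Two design choices matter:

* **Null invariance over at-risk bookkeeping.** Removing
  ICU-transferred (or DNR-terminated) patients from the at-risk pool
  would make a θ = 1 intervention arm differ from control, because
  escalation occurs only when the system is on. Transfer and
  termination are therefore recorded in the trajectory but do not stop
  the hazard draws: the admission's arrest risk follows the admission.
  With per-admission RNG sub-streams (hazard uniforms drawn before
  escalation uniforms) the θ = 1 arms are *byte-identical*, and a
  θ < 1 arm's events are a coupled subset of control — a strong,
  cheaply testable form of the null-invariance requirement.
* **What θ recovery means.** Only warning-zone-reaching, non-DNR
  admissions are treated, so `estimate_rate_ratio()` estimates θ on
  that subgroup. Under this calibration ~5% of admissions reach the
  zone, so a post-alert-only mechanism moves the *overall* rate ratio
  to only ≈ 0.82 at θ = 0.46 — the observed overall drop from 5.21 to
  2.39 per 1000 cannot be produced by this mechanism alone. That is a
  substantive limitation of the single-mechanism model (and arguably
  of attributing the whole observed drop to post-alert treatment),
  stated here rather than tuned away.

The simulator steps the state machine on the generator's per-day
intended maxima rather than re-realizing and re-scoring ~200,000
vital-sign rows per arm; the vitals layer's equivalence is exactly the
round-trip property tested separately, and `generate_cohort()` still
produces full vitals for pipeline and IO tests.

## Reproducibility and limitations

Everything stochastic flows from one integer seed; cohorts are
byte-identical across runs, and every CLI run writes a manifest
(command, input checksums, config echo, seed, version). Known
limitations, beyond those above: the before/after contrast has no
concurrent control, so the synthetic intervention effect demonstrates
parameter recovery, not causal identification; stratum tests are
unadjusted for multiplicity; deaths are independent of scores; and the
generator's monthly admission weights are uniform, so it does not
reproduce real seasonal census variation.
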
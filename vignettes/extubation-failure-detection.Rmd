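---
title: "Detecting extubation failure from ICU flow-sheet charting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting extubation failure from ICU flow-sheet charting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extufail)
```

## The problem

Extubation failure — needing endotracheal reintubation within 72 hours of a
prior extubation — is a consequential ICU outcome, yet finding it in
retrospective data usually means reading charts. Nurse-charted flow sheets
record airway state as structured rows ("Airway Tube Status" with values
like *Intubated*, *Extubated*, *Inserted*; "Airway Tube Type" with
*Endotracheal tube*, *Tracheostomy*, *Nasal trumpet*, ...), which makes the
outcome computable: a temporal rule over those rows can classify a patient
without manual review. This package implements that rule, the accuracy
machinery used to validate it against manual review, and a synthetic
flow-sheet generator for exercising both.

## The detection rule and its assumptions

Charted rows are first normalized into airway events. A status value is
matched **case-insensitively and whole-token** against closed vocabularies:
{*extubation*, *extubated*} → `EXTUBATION`, {*intubation*, *intubated*,
*inserted*} → `INTUBATION`, anything else → `OTHER`. Token matching (not
substring) reflects that flow-sheet fields are picklist-like designations:
*re-intubated* deliberately does **not** match *intubated*. Each intubation
event receives a tube type from the "Airway Tube Type" row charted at the
identical timestamp, else the nearest such row within ±60 minutes (a
distance tie resolves to the earlier charting), else `UNKNOWN`. The
association window is a package convention — charting practice does not
guarantee the two rows share a timestamp, and ±60 min spans one charting
cycle; it is tunable via `assoc_window_min`.

A **signature** then classifies the patient:

* `initial_signature()` — some extubation is followed by an intubation with
  `0 < Δt ≤ 72 h` (both endpoints of the window are conventions: `Δt = 72 h`
  inclusive because the definition says *within 72 hours*; `Δt = 0` excluded
  so simultaneous chartings never pair). Each intubation is paired with its
  most recent prior extubation, so one reintubation cannot pair with a stale
  extubation further back. Both events must be ICU-charted (same admission),
  excluding intubations performed in the operating room or emergency
  department.
* `final_signature()` — additionally requires the intubation's tube type to
  be `ENDOTRACHEAL`. This is a pure conjunctive restriction: a
  final-signature positive is always an initial-signature positive, and its
  only effect on a 2×2 table against fixed gold labels is to remove
  positives.

When `icu_only` is active, the whole event stream is restricted to
ICU-located events *before* pairing, so an out-of-ICU extubation neither
starts a pair nor interrupts one. The verdict is patient-level: any
qualifying pair makes the patient positive, with the first pair kept as
evidence.

Two limitations are inherent and reproduced faithfully: a rule can only see
what was charted (an extubation recorded with a non-matching token such as
*Removed* is invisible, producing false negatives), and it cannot read
intent (an accidental extubation promptly reintubated, or a brief
procedural reintubation, is a genuine endotracheal reintubation within the
window and will be flagged even though chart reviewers do not count it as
extubation failure).

## Cohort handling

Eligibility mirrors the usual adult-ICU inclusion: age ≥ 18 years and
mechanical ventilation ≥ 48 hours during the ICU admission, both thresholds
inclusive, with ventilation hours supplied as metadata (no inference from
ventilator rows — those are also charted for noninvasive ventilation and
tracheostomy support). Records missing eligibility metadata are excluded
conservatively with a warning. `filter_cohort()` logs and attaches the
funnel counts; `sample_subset()` draws seeded uniform subsets for
derivation/validation splits (disjointness is the caller's responsibility).

## Accuracy statistics

`confusion()` tabulates patient-level calls against gold labels;
`accuracy_report()` derives sensitivity, specificity, PPV, NPV (each with a
confidence interval) and prevalence. Denominator identities are enforced by
construction (e.g. sensitivity trials = TP+FN); a metric with a zero
denominator is reported absent rather than 0 or an error, so degenerate
tables stay interpretable.

The default interval is the **Wilson score interval with continuity
correction** at z = 1.96 — the method behind the classic online clinical
calculators that rule-based phenotyping studies report, and the method
whose endpoints integer-round to the values such studies print. z is fixed
at 1.96 rather than `qnorm(0.975)` = 1.959964 to mirror those calculators;
the difference never moves an integer percent. The equal-tailed
Clopper–Pearson exact interval (`method = "clopper_pearson"`, via the
beta-quantile closed form) is provided because "exact test for proportions"
is the label such studies often use; its test oracle is an independent
tail-sum inversion of the binomial distribution. Boundary conventions:
0 successes pin the lower limit at 0, all-successes pin the upper at 1, and
human-readable output rounds half away from zero to integer percent
(92.857% → 93%). Note that integer-percent rendering of a CI endpoint can
disagree with historical hand-rounding (99.63% renders 100%, not 99%); the
package applies its rule uniformly.

```{r ci}
wilson_cc_interval(12, 14)
clopper_pearson_interval(12, 14)
```

## What the generator emulates

`generate_cohort()` produces per-patient charting with a common skeleton —
ICU admission, intubation one hour in (status + endotracheal tube type),
48–160 h of ventilation, extubation — followed by one scenario:

| scenario | charting after extubation | gold | detector behavior |
|---|---|---|---|
| `TRUE_FAILURE` | endotracheal reintubation, delay U(1, 72) h | positive | both signatures flag |
| `LATE_REINTUBATION` | endotracheal reintubation, U(73, 120) h | negative | neither flags |
| `NO_REINTUBATION` | nothing | negative | neither flags |
| `NASAL_TRUMPET` | "Inserted" + nasal-trumpet type, ≤ 72 h | negative | initial-only false positive |
| `ACCIDENTAL_EXTUBATION` | prompt reintubation, U(0.1, 1) h | negative | false positive for both |
| `PROCEDURAL_REINTUBATION` | reintubation then re-extubation U(0.5, 2) h later | negative | false positive for both |
| `MISCODED_STATUS` | extubation charted as "Removed", then reintubation | positive | false negative for both |
| `OR_INTUBATION_ONLY` | reintubation charted in the OR | negative | neither flags |
| `TRACHEOSTOMY` | reintubation with tracheostomy type | negative | initial-only false positive |

Gold labels are fixed per scenario; accidental and procedural reintubations
are gold-negative because chart reviewers do not count them as extubation
failure, which is precisely what makes them irreducible false positives for
any charting-level rule. The delay distributions are conventions chosen to
respect the stated bounds (prompt ≲ 1 h; procedural < 2 h intubated; late
strictly beyond the window), not estimates of real charting cadence — real
flow sheets also re-chart tube types between events, chart far more
`OTHER`-class rows, and contain multi-admission patients, none of which the
generator attempts. Passing tests therefore demonstrate the rule's logic
and bookkeeping, not its operating characteristics on any real ICU's data.
All timestamps are minute-resolution in a single implicit timezone;
scenario assignment is an i.i.d. draw from the config mix, so realized
prevalence is binomial around the configured value, and a `cohort_config`
whose gold-positive scenario mass contradicts its stated prevalence is
rejected.

Two deterministic 100-patient fixtures (fixed internal seeds, fixed
scenario counts) package the canonical derivation and validation
structures:

* `fixture_derivation()` — 12 clean failures + 2 miscoded (14
  gold-positives), 4 nasal trumpets, 82 clean negatives. The initial
  signature yields TP=12, FP=4, FN=2, TN=82 (6 disagreements); the final
  signature removes exactly the 4 nasal-trumpet false positives.
* `fixture_validation()` — 15 clean failures + 1 miscoded, 2 accidental + 2
  procedural reintubations, 80 clean negatives: the final signature
  disagrees with gold for exactly 5 patients (4 FP, 1 FN), sensitivity
  15/16 → 94%.

Because the final signature is a pure restriction, it cannot *gain* a true
positive over the initial signature on fixed labels; the derivation fixture
accordingly reports final-signature sensitivity 12/14 (86%), with the
13/14 (93%) sensitivity table exercised directly through
`accuracy_report()`.

```{r fixtures}
der <- fixture_derivation()
calls <- classify_cohort(der$records, final_signature())
confusion(calls, der$manifest[, c("patient_id", "gold_label")])
```

## Design choices and problem sizes

Open points were settled as follows: timestamps are ISO 8601 at minute
resolution in one implicit timezone; flow-sheet values are treated as
picklist-like tokens; `vent_duration_h` is supplied metadata; patients
lacking a gold label are excluded from accuracy computation but still
classified; duplicate patient ids in a 2×2 computation are an error rather
than silently collapsed. The property-based suite checks the detector
against an exhaustive pair-enumeration oracle on 1,000+ random event
streams of up to 10 events, Clopper–Pearson endpoints against tail-sum
inversion for all n ≤ 30, simulated Wilson-CC coverage at n = 14, p = 0.85
over 10,000 draws (≥ 0.95; the continuity correction is conservative —
exact enumeration gives 0.988), and recovery of a planted 0.14 prevalence
within 3 binomial standard errors at n = 1,000. These sizes keep the full
suite under a minute while leaving each property's failure modes
well-sampled.

## Known limitations

The detector is patient-level (no episode-level outcome analysis), assumes
one admission per record for pairing, does not parse narrative notes or
HL7/FHIR feeds, and inherits every documentation failure of the underlying
flow sheet: miscoded status tokens are undetectable in principle, and
gold-negative genuine reintubations are flagged in principle. The generator
is a mechanism model of charting, not of ICU physiology; institutional
funnels (tens of thousands of admissions reduced to a ventilated adult
cohort) are represented only by the seeded eligibility-filter demo at
desk scale.
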
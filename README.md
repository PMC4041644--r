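# extufail

Rule-based detection of **extubation failure** — endotracheal reintubation
within 72 hours of a prior extubation — from nurse-charted ICU flow-sheet
rows, together with the derivation/validation accuracy machinery used to
evaluate such computable phenotypes against manual chart review.

## Who this is for

Critical-care and clinical-informatics researchers who need to find
reintubation episodes in electronic flow-sheet data ("Airway Tube Status",
"Airway Tube Type" rows) without reading charts, and who need defensible
sensitivity/specificity reporting for the resulting phenotype. The package
also ships a synthetic flow-sheet generator that plants the charting
patterns known to fool such rules, so the detector can be exercised with
known ground truth.

## The algorithm

A patient is flagged by a **search signature** over their normalized airway
events:

- **Initial signature** — an `EXTUBATION` event (status value
  token-matching *extubation/extubated*) followed by an `INTUBATION` event
  (status *intubation/intubated/inserted*) with
  `0 < Δt ≤ 72 h`, both charted in the ICU during the same admission, the
  intubation paired with its most recent prior extubation.
- **Final signature** — the initial signature **and** the intubation's
  associated "Airway Tube Type" is *endotracheal tube* (eliminating nasal
  trumpets, tracheostomies, nasotracheal tubes).

Patient-level calls are compared with gold labels in a 2×2 table, and
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV, NPV and prevalence
are reported with 95% **Wilson score intervals with continuity correction**
(z = 1.96; Clopper–Pearson available via `method = "clopper_pearson"`).

## Worked example

```r
library(extufail)
dir <- tempfile()
cmd_simulate(dir, fixture = "derivation")          # packaged 100-patient cohort
calls <- cmd_detect(file.path(dir, "flowsheet.csv"),
                    file.path(dir, "metadata.csv"),
                    signature_name = "initial",
                    out = file.path(dir, "calls.csv"))
cmd_validate(file.path(dir, "calls.csv"), file.path(dir, "metadata.csv"))
```

prints

```
Simulated 100 patients (14 gold-positive) into ...; scenarios: LATE_REINTUBATION=16, MISCODED_STATUS=2, NASAL_TRUMPET=4, NO_REINTUBATION=66, TRUE_FAILURE=12
Parsed 395 flow-sheet rows into 100 patient records
Cohort funnel: 100 in; 0 missing metadata, 0 under age 18, 0 under 48 vent-hours; 100 retained
INITIAL signature: 16 of 100 patients positive
Signature: INITIAL
Accuracy report (n=100, wilson_cc intervals)
  TP=12 FP=4 FN=2 TN=82
  Sensitivity 86% (95% CI, 56%-97%)
  Specificity 95% (95% CI, 88%-98%)
  PPV         75% (95% CI, 47%-92%)
  NPV         98% (95% CI, 91%-100%)
  Prevalence  0.14
```

Of the 16 initial-signature positives, 4 are nasal-trumpet insertions
charted as "Inserted" after extubation; rerunning with
`signature_name = "final"` removes all 4 (specificity 100%) while the 2
patients whose extubation status was miscoded remain undetectable by either
signature. A shell front end with the same subcommands
(`detect`/`validate`/`simulate`/`ci`) is installed at
`system.file("cli", "extufail.R", package = "extufail")`.

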
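# apqi — disease-specific antibiotic prescribing quality indicators for out-of-hours primary care

Out-of-hours (OOH) general practice sees a high volume of infections, most
of them self-limiting, yet antibiotics — and notably broad-spectrum drugs
and quinolones — are prescribed far more often than guidelines support.
`apqi` implements the disease-specific **antibiotic prescribing quality
indicators (APQI)** introduced by the European Surveillance of Antimicrobial
Consumption (ESAC) project for routine appraisal of encounter-level
electronic health record extracts from OOH general practitioner
cooperatives (GPCs). It is aimed at quality-of-care researchers and
audit-and-feedback programmes working with ICPC-2-coded diagnoses and
ATC-coded prescriptions.

## The indicators

For each indication *d* (an ICPC-2 diagnosis with an age/sex eligibility
window, e.g. *female patients ≥ 18 years with cystitis, U71*), three values
are computed over eligible encounters:

- **a** = 100 · n_ab / n_eligible — % of eligible patients prescribed an
  antibiotic (ATC J01),
- **b** = 100 · n_recommended / n_ab — % of treated patients receiving the
  guideline-recommended antibiotic (a configurable ATC prefix set),
- **c** = 100 · n_quinolone / n_ab — % of treated patients receiving
  quinolones (ATC J01M),

each classified against an acceptable range (e.g. a < 20% for upper
respiratory infections, b > 80%, c < 5%) and bracketed by the min–max over
sites, the audit-and-feedback signal for individual GPCs. Alongside the
indicators, the package describes prescribing by indication and ICPC-2
chapter and applies a DU90%-style appraisal: how many indications are
needed to cover 90% of all antibiotic prescriptions, and how much the APQI
set itself covers. The nine-indication default configuration includes the
two disease entities proposed for OOH care, erysipelas (S76) and teeth/gum
disease (D82).

Because clinical OOH databases are not public, the package ships a
seed-reproducible synthetic encounter generator whose default scenario is
calibrated to published Belgian OOH aggregates (five GPCs, 111,600
consultations, 26,436 antibiotic prescriptions over two years), so the
entire pipeline is testable end to end.

## Worked example

```r
library(apqi)
cfg     <- apqi_config()                   # nine indications, editable YAML
records <- generate_encounters(default_scenario(), n = 20000, seed = 42)
results <- compute_indicators(records, cfg)
format_indicator_table(results)
```

```
  icpc  label                                   prescribed        recommended      quinolones
1 H71   Acute otitis media / myringitis         63 [53-72] ABOVE  74 [70-77] BELOW  1 [0-2] WITHIN
2 R74   Acute upper respiratory tract infection 32 [21-44] ABOVE   4 [3-5] BELOW    2 [1-2] WITHIN
3 R75   Acute / chronic sinusitis               51 [40-65] ABOVE  36 [29-41] BELOW 10 [5-21] ABOVE
4 R76   Acute tonsillitis                       75 [67-86] ABOVE   7 [3-11] BELOW   1 [1-4] WITHIN
5 R78   Acute bronchitis / bronchiolitis        74 [57-81] ABOVE  41 [34-50] BELOW 11 [7-14] ABOVE
6 R81   Pneumonia                               78 [67-89] BELOW  46 [32-80] BELOW 15 [0-31] ABOVE
7 U71   Cystitis / other urinary infection      92 [84-98] WITHIN 66 [64-72] BELOW 27 [15-29] ABOVE
8 S76   Erysipelas                              78 [75-84] BELOW  46 [43-51] BELOW  2 [0-4] WITHIN
9 D82   Teeth / gum disease                     64 [54-80] ABOVE  46 [40-52] BELOW  1 [0-5] WITHIN
```

Each cell is `pooled-% [min–max over sites] classification-vs-acceptable-
range`. Read: 75% of eligible tonsillitis patients received an antibiotic
(acceptable < 20%, so ABOVE), only 7% of those treated got the recommended
narrow-spectrum penicillin (acceptable > 80%, BELOW), and quinolone use for
cystitis (27%) far exceeds the 5% ceiling — the patterns the synthetic
scenario is calibrated to emulate.

```r
links <- link_prescriptions(records)
coverage_of_set(links, apqi_codes("apqi9"))
#> <apqi_coverage> 4889 antibiotic prescriptions; set {R78, R74, U71, R76, R75, H71, R81, S76, D82} covers 3202 (65.5%)
#>   18 top diagnoses needed to cover 90% of prescriptions
#>   missing diagnosis: 5.4%; symptom diagnosis: 3.5%
```

So even the extended nine-indication set describes about two-thirds of
antibiotic prescribing — well short of the DU90% ideal — which is the
critical-appraisal message the coverage module quantifies.
`build_report()` assembles these results (optionally against a reference
value table such as `inst/extdata/reference-values-2004-2009.csv`) into a
JSON + markdown feedback report per the single-source-of-truth principle.

## Data dictionary

Input files are delimited text, one row per consultation:
`site_id`, `encounter_id`, `date` (ISO-8601), `age_years` (completed years,
fractional for infants), `sex` (`F`/`M`/`U`), `icpc`
(semicolon-separated ICPC-2 codes, empty = missing diagnosis), `atc`
(semicolon-separated ATC codes, empty = none). Only consultations at the
cooperative itself should be supplied (home visits are not special-cased).
`read_encounters()` validates every row and reports exclusions; see the
vignette for conventions (age boundaries, b/c denominators, rounding).
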
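---
title: "Methods: disease-specific antibiotic prescribing quality indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-specific antibiotic prescribing quality indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apqi)
```

## The appraisal model

`apqi` appraises antibiotic prescribing quality in out-of-hours (OOH)
primary care at the level of the consultation. The unit of observation is
an encounter at a general practitioner cooperative (GPC) carrying zero or
more ICPC-2 diagnosis codes and zero or more ATC prescription codes. Two
complementary views are computed.

**Disease-specific indicators.** For an indication $d$ with eligibility
window $E_d$ (ICPC-2 code, age limits, sex restriction), over the eligible
encounters:

$$a_d = 100\,\frac{n_{ab}}{n_{eligible}},\qquad
  b_d = 100\,\frac{n_{recommended}}{n_{ab}},\qquad
  c_d = 100\,\frac{n_{quinolone}}{n_{ab}}$$

where an encounter counts in $n_{ab}$ when at least one of its
prescriptions falls under ATC J01 (antibacterials for systemic use), in
$n_{recommended}$ when at least one prescription prefix-matches the
indication's recommended set, and in $n_{quinolone}$ when at least one
falls under J01M. An encounter can count in both $n_{recommended}$ and
$n_{quinolone}$. Each value is classified against a closed acceptable
range and bracketed by the min--max over sites.

**Indication coverage.** Every prescription is linked to the diagnosis
registered in the same consultation (missing when none was registered).
Antibiotic links are tabulated by indication and by ICPC-2 chapter, and a
drug-utilization-90% style statistic is adapted from drugs to indications:
the minimal number of top-ranked diagnoses whose cumulative share reaches
90% of all antibiotic prescriptions. This quantifies whether an indicator
set describes "enough" of total prescribing to serve as a quality summary.

## Assumptions and conventions

These are points the indicator literature leaves open; the package fixes a
default and exposes the alternative where one is defensible.

* **Encounters stand in for patients.** OOH extracts carry no patient
  identifier that is stable across sites, so denominators are encounters.
  With repeat visits for the same episode this slightly inflates
  denominators; the synthetic generator makes the same assumption.
* **Age boundaries** (`options$age_boundary`). "Older than $N$ years" is
  read as completed age $\ge N$ (`"inclusive"`, the default, matching
  common indicator usage); `"strict"` gives $> N$. Intervals such as
  "between 18 and 75" are inclusive on both ends either way.
* **Denominator of b and c** (`options$bc_denominator`). The phrase
  "b = a and receiving the recommended antibiotic" is ambiguous between a
  share of eligible patients and a share of treated patients. The default
  conditions on treatment (`"treated"`): acceptable ranges like
  $b > 80\%$ are only coherent on that denominator (upper-RTI prescribing
  of 30% could never reach $b > 80\%$ of eligible). `"eligible"` exposes
  the unconditional variant for sensitivity analyses.
* **Multiple diagnoses per consultation.** A prescription is linked to the
  first-listed diagnosis and the encounter flagged, preserving the
  identity *links = prescriptions* that the descriptive tables rely on;
  `to_all_diagnoses = TRUE` duplicates links for sensitivity analyses.
* **Symptom diagnoses.** ICPC-2 rubrics 01--29 (component 1: symptoms and
  complaints, e.g. fever A03, cough R05) are never indicator
  denominators; their share of antibiotic links is reported descriptively.
  The rubric boundary is a convention of this package, since the indicator
  definitions themselves do not state one.
* **Recommended sets are data, not code.** The guideline-recommended
  antibiotics per indication are a YAML configuration
  (`inst/extdata/apqi-indicators.yaml`), not hard-coded clinical truth.
  The defaults follow Belgian first-line guidance: narrow-spectrum
  penicillin (J01CE) for tonsillitis and upper RTI, amoxicillin (J01CA04)
  for otitis media, sinusitis, bronchitis, pneumonia and dental infection,
  nitrofuran derivatives (J01XE) for cystitis, beta-lactamase-resistant
  penicillins (J01CF) for erysipelas. Membership is by ATC prefix so sets
  can be written at any level; whether a guideline means "first-line only"
  or "any acceptable choice" is encoded by simply listing more or fewer
  prefixes. Tests assert the mechanics of the lookup, not the clinical
  content of the defaults.
* **Rounding.** Values are computed at full precision, classified
  unrounded (avoiding boundary artifacts at range edges), stored to one
  decimal, and displayed to whole percent by `format_indicator_table()`.
* **Degenerate inputs.** Zero denominators yield `NA` values classified
  `UNDEFINED`, never errors; sites without eligible encounters are
  excluded from brackets and listed.

## The synthetic scenario

`default_scenario()` emulates two years of Belgian OOH encounters across
five GPCs. It is a *calibration*, not a simulation of disease dynamics:

* Per-indication prescribing probability, recommended fraction and
  quinolone fraction equal published pooled indicator values (as
  probabilities) for the nine indications — e.g. tonsillitis $p = 0.77$,
  otitis-media recommended fraction $r = 0.74$, cystitis quinolone
  fraction $q = 0.25$.
* Encounter shares of the indicator diagnoses are back-computed as
  published prescription count $/\,(p \times 111{,}600)$, so the generated
  prescription mix reproduces the published indication mix; 6% of
  encounters carry no diagnosis and ~4% a symptom rubric, and the
  remaining mass is spread over common non-indicator infections so chapter
  shares resemble the published chapter table. The implied overall rate is
  ~23.7 antibiotic prescriptions per 100 encounters.
* Five sites are weighted by the published catchment populations. Site
  heterogeneity enters as multiplicative odds adjustments (0.6--1.6) on
  the prescribing probability only; the adjustments roughly span the
  published between-site brackets while keeping the population-weighted
  pooled value within ~0.1 percentage point of the calibrated probability
  (the logistic transform is nonlinear, so wilder multipliers would bias
  the pooled value).
* Ages are drawn from per-diagnosis child/adult/elderly mixtures chosen to
  cross every eligibility boundary (toddlers below the otitis-media
  minimum, patients over 75 with bronchitis, males with cystitis), so
  eligibility filters are exercised on both sides. Drug-class draws map to
  one representative ATC code per class per indication; the broad-spectrum
  alternative is chosen so it never prefix-matches the same indication's
  recommended set.
* Each encounter consumes a fixed block of nine uniforms from one seeded
  Mersenne-Twister stream, so output is byte-identical across runs and a
  shorter run is a prefix of a longer one.

What the generator does **not** model — and what passing tests therefore
do not show about real data: seasonality and epidemics, repeat visits and
episode structure, delayed prescriptions, correlated comorbidity,
free-text or miscoded diagnoses beyond a flat missing/symptom mass, and
site differences in anything but prescribing propensity. Recovery of the
calibrated parameters demonstrates that the engine measures what the
generator encodes, not that the defaults describe any particular health
system.

## Verification design

* **Oracle equivalence.** On record sets of up to 50 encounters the
  engine is compared, count for count, against an independent brute-force
  implementation written with nested loops and `substr()` prefix checks.
* **Parameter recovery.** For each of the nine indications a
  single-indication, homogeneous-site scenario with 50,000 encounters must
  recover $a$, $b$ and $c$ within 1.5 percentage points (about five
  binomial standard errors). The end-to-end check runs the full
  heterogeneous default scenario at $n = 100{,}000$ — chosen because
  tonsillitis is only ~2.7% of encounters, so smaller runs leave the
  binomial noise of its recovered $a$ near the 2-point check itself — and
  requires the pooled tonsillitis $a$ and otitis-media $b$ within 2 points
  of their calibrated values.
* **Published arithmetic.** A count-table fixture reproduces published
  coverage and share arithmetic exactly (the seven-indication covered
  count 14,927; chapter and indication shares after printed rounding). The
  published sub-3% remainder is shipped as a synthetic disaggregation
  (marked as such) consistent with the published chapter totals and
  symptom share; where a published rounded percentage conflicts with its
  own printed counts (56.7% vs 14,927/26,436 = 56.5%; 66% vs 65.3% for
  nine indications), the package reports the exact ratio and surfaces the
  count.
* **Structural properties.** Conservation of antibiotic-link counts
  across chapter, ranking and coverage tables; monotonicity of $a$ under
  adding treated/untreated eligible encounters; closed-bound
  classification consistency; byte-identical regeneration under fixed
  seeds; write/read round-trip stability.

Problem sizes in the shipped suite (50,000-encounter recovery runs,
100,000-encounter end-to-end run, ten 50,000-encounter calibration
replicates) were chosen so each stochastic tolerance sits at roughly five
standard errors of its estimator.

## Known limitations

Eligibility uses completed age only (no months granularity beyond the
decimal); recommended sets cannot express dose, duration or second-line
logic, only ATC membership; coverage keeps missing-diagnosis prescriptions
in the denominator (as the published arithmetic does) but does not count
"missing" as a diagnosis toward the 90% statistic, so heavily under-coded
data can make 90% unreachable (reported as `NA`); and the indicator values
carry no inferential statistics — they are audit quantities, and the
between-site brackets are ranges, not confidence intervals.
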
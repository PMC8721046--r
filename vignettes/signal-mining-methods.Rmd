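---
title: "Methods: descriptive severity analysis and disproportionality signal mining for spontaneous ADR reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptive severity analysis and disproportionality signal mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsmine)
```

## The data model and its assumptions

`srsmine` analyses individual case safety reports (ICSRs) from a
spontaneous reporting system (SRS). An SRS is a passive surveillance
instrument: reporters (mostly clinicians) submit a record when they suspect
a drug caused a reaction. Three consequences shape everything the package
computes:

* the denominator (patients exposed) is unknown, so every statistic is a
  *frequency of reporting*, never an incidence;
* reports are noisy — duplicated, incomplete, implausible records occur —
  so filtering with an auditable trail is a first-class step;
* causality is the reporter's assessment, recorded on the report; the
  package takes the causality category as given and never re-derives it.

A report carries: identifier, reporting year, age (integer years), gender,
causality category, one or more suspected drugs with ATC codes, the total
medication count, one or more coded ADR terms each with a per-term serious
flag, the set of regulatory seriousness criteria, the number of diagnoses
before the reaction, past ADR history, onset lag in days (0 = same day),
route, and an off-label flag (the union of outside-licensed-age and
outside-licensed-indication use; the package does not re-derive it from
licensing data).

### Severity

A report is **serious** if and only if at least one of six regulatory
criteria applies: death; life-threatening; carcinogenesis, teratogenesis or
congenital disability; persistent or significant disability; inpatient
hospitalization or its prolongation; or another important medical event.
This definition is monotone by construction: adding a criterion can never
demote a serious report.

### One pair per report

A report may list several reactions, but the analysis unit is a single
(primary drug, primary ADR) pair per report — the same convention the
descriptive tables and the contingency tables both rely on, which keeps
the DEC tables a partition of the corpus. The default selection policy
ranks serious-flagged terms above non-serious ones and breaks ties by
listing order; the policy is an explicit argument of
`select_primary_adr()` so an analysis can swap it and say so.

## Filtering

`apply_inclusion_filters()` implements the inclusion/exclusion rules of a
pediatric antineoplastic extract: reporting year 2016–2020, causality in
{certain, probable, possible}, at least one suspected drug in ATC class
L01, age 0–17, plausibility checks (age not above 120, non-negative onset
lag), critical fields present, duplicates removed (default key: report
identifier; any field combination can be supplied instead). Every rejected
record is attributed to the *first* rule that rejects it, in a fixed
documented order, so the audit is deterministic and satisfies
`n_in = n_out + sum(removed)` on any input; filtering is idempotent.
Records with unmapped drug or event strings are *not* dropped — they fall
through coding with a warning; removal is exclusively the filter stage's
job.

Age 0 is inside the inclusion window but outside the youngest analysis bin
(1–3 years); such records are retained for totals and flagged with a
missing age bin rather than silently excluded.

## Descriptive severity analysis

`build_stratified_table()` cross-tabulates one characteristic (gender, age
group, single/multiple disease, past ADR history, onset bin, polypharmacy
at the ≥2 and ≥5 thresholds, route, off-label) against severity, computes
row percentages (rounded half-up to one decimal, the printing convention
used throughout), and tests independence.

Two numerical choices matter:

* **No continuity correction** in the Pearson chi-square. The stratified
  tables of the reference corpus reproduce their printed p-values (0.008
  for past ADR history, 0.423 for gender, 0.622 for disease types, 0.407
  for off-label use) only with the uncorrected statistic, so the module
  default is `chisq.test(correct = FALSE)`.
* **Test choice** follows the Cochran rule: Fisher's exact test when any
  expected cell of a 2×2 — or more than 20% of expected cells of an r×c
  table — is below 5; Pearson otherwise. On the reference corpus this rule
  selects exactly the tests the published tables footnote (Fisher for the
  6×2 onset table and the 3×2 route table, chi-square elsewhere). A
  per-characteristic override is available for corpora where it does not.

Fisher's exact test is the exact hypergeometric two-sided test for 2×2
tables and the Freeman–Halton network algorithm for r×c; if the network
evaluation exceeds its workspace budget the implementation falls back to a
*seeded* Monte Carlo p-value (default 10⁵ resamples) and reports the
Monte Carlo standard error alongside. The test suite checks the 2×2 path
against an independent brute-force enumeration of all tables with the
observed margins.

P-values display with three decimals, rendering below 0.0005 as
`"<0.001"`. Quartiles use R's default linear-interpolation convention
(`quantile(type = 7)`); the convention is fixed and documented so printed
medians and IQRs are reproducible. Records with an unknown category are
excluded from that characteristic's table only (and counted), never from
the corpus.

No multiplicity adjustment is applied across characteristics, and no
multivariable model is fitted — the descriptive module mirrors a
univariate screening analysis; this is a deliberate scope boundary, noted
rather than corrected.

## Disproportionality statistics

For each observed DEC, with `a, b, c, d` as in the README and
`n = a+b+c+d`:

* `ROR = ad/bc`, `PRR = [a/(a+b)]/[c/(c+d)]`, each with
  `CI = exp(log(est) ± z·sqrt(1/a+1/b+1/c+1/d))`, `z = 1.96`;
* MHRA criterion: `χ² = n(|ad−bc|−n/2)²/[(a+b)(c+d)(a+c)(b+d)]`, the
  Yates-corrected chi-square, with the continuity term clamped at zero so
  independent tables score exactly 0. A zero marginal carries no
  association information; the statistic is defined as 0 with a warning.

Flag rules (all configurable): ROR — `a ≥ 3` and CI-low > 1; PRR —
`a ≥ 3`, `PRR ≥ 2`, CI-low > 1; MHRA — `a ≥ 3`, `χ² ≥ 4`. The combined
flag defaults to *all three methods agreeing*; `any` and `majority` rules
are provided because published analyses are often ambiguous about the
aggregation, and the rule used is echoed in the output metadata.

Zero cells leave ROR/PRR undefined by default — the printed formulas carry
no correction, and silently shifting estimates would misstate them; the
Haldane–Anscombe +0.5 correction is available as an explicit option. The
background for `b, c, d` is the analysis corpus itself (the filtered
pediatric extract); mining against an external background corpus is a
legitimate variant but changes the question being asked, so it is left to
the caller's data preparation.

Structural properties asserted in the tests: the ROR is invariant under
transposing the table (swapping `b` and `c`) while the PRR is not;
`ROR − 1` and `PRR − 1` always share their sign, with the ROR the more
extreme of the two above 1; and the MHRA statistic coincides with an
independent Yates-corrected chi-square implementation on a thousand random
tables.

## The synthetic corpus generator

Because real SRS extracts of this kind are not redistributable, the
package ships a generator (`generate_corpus()`) whose defaults emulate the
published marginal structure of a 431-report pediatric antineoplastic
corpus: ten drugs with shares led by cytarabine (≈26%), twenty ADR terms
led by myelosuppression (≈16%) each mapped to a system organ class, age
groups peaking at 1–3 years, ≈62% male, ≈10% past ADR history, ≈6%
multi-disease, ≈94% parenteral route, ≈7% off-label, onset concentrated
within one week (≈80%), and a medication-count distribution yielding ≈49%
polypharmacy (≥2) and ≈7% at the conservative ≥5 threshold.

Sampling is transparent by design: the drug is drawn from its marginal;
the event from the event marginal *re-weighted by the multiplier for
injected pairs and renormalized within the drug* — under this scheme an
injected multiplier `m` implies a true ROR of exactly `m`, which
`true_dec_stats()` returns analytically. Severity is drawn from a logistic
model on past history, polypharmacy (both thresholds) and late onset
(≥8 days), with coefficients (0.85, 0.80, 0.75, 1.40) sized from the
published stratified odds ratios and an intercept of −1.69 calibrated once
so the marginal serious share is ≈31.5%. All fields are sampled in a fixed
order from a single seed, so a corpus is a deterministic function of
(configuration, seed). Generated corpora pass the default filters by
construction; `corrupt_corpus()` plants year/causality/age/lag/blank-field
defects and duplicates at stated rates, with a ledger that the filter
audit recovers exactly.

What the generator does **not** model: reporting propensity and
under-reporting dynamics, reporting delays, drug–drug interactions,
correlations between demographics and drug choice, multiple suspected
drugs per report. Passing tests on synthetic corpora therefore validate
the *statistical machinery* — not any claim about a real population.

## Validation experiments and their problem sizes

The test suite and `scripts/acceptance.R` run four seeded experiments,
sized to finish in about a minute while leaving clear statistical margin:

* **CI coverage** — 2,000 multinomial corpora of 500 reports with cell
  probabilities (0.04, 0.06, 0.10, 0.80) (true odds ratio 16/3, all
  expected cells ≥ 5); the 95% ROR interval covers the truth in 93–97% of
  corpora.
* **Sensitivity** — 500 corpora of 2,000 reports with one injected pair at
  multiplier 8 (expected `a` ≈ 13); the combined flag recovers it in well
  over 95% of replicates.
* **Null false flags** — 10 corpora of 50,000 reports over a uniform
  50-drug × 50-event vocabulary (expected count 20 per pair); combined
  flags per corpus average well under 2. The corpus size matters: at a few
  thousand reports the expected pair count drops to ~1 and the
  `PRR ≥ 2` / `a ≥ 3` gates fire tens of times per corpus under the null
  — the familiar small-count instability of disproportionality statistics,
  and the reason flagged DECs at small `a` deserve skepticism rather than
  alarm.
* **Parameter recovery** — one corpus of 50,000 reports; a logistic
  regression of severity on the generator's covariates recovers all
  coefficients within ±0.1 (observed errors are a few hundredths).

## Known limitations

* Signal flags are screening statistics, not causal claims; false
  positives are expected at small counts and no shrinkage (Bayesian
  disproportionality) is implemented.
* The drug dictionary and SOC map are simplified user-supplied surrogates
  for licensed terminologies (ATC catalogues, MedDRA); the shipped
  defaults only cover the generator's vocabulary.
* The descriptive module reproduces a univariate screening analysis;
  confounding between characteristics (for instance polypharmacy and
  onset) is not addressed.
* Proportions are of *reports*, not patients or exposures; nothing in the
  package can correct for the unknown population at risk.
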
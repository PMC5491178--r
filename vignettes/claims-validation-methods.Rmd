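---
title: "Methods: validating claims-based case ascertainment for pediatric celiac disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating claims-based case ascertainment for pediatric celiac disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celiacclaims)
```

## The estimation problem

Administrative claims identify a child as a celiac disease (CD) "case" only
through coded traces of the diagnostic process: an endoscopy procedure code
followed by outpatient visits or hospitalizations carrying a CD diagnostic
code. The package formalizes such rules, measures their diagnostic accuracy
against a reference standard in which true biopsy-proven status is known,
and propagates ascertained cases into standardized incidence and trend
estimates. Everything operates on a `claims_bundle`: five linked tables
(registry with coverage-eligibility intervals, outpatient claims,
same-day-surgery procedure records, hospital discharges, physician
specialties) plus an optional label table giving each child's reference
status, diagnosis date and Marsh grade.

Two structural facts about the data drive the whole design:

* an outpatient claim carries exactly **one** diagnostic code, assigned at
  billing time — before histology is available — so endoscopy fee claims
  are treated as indication-blind;
* a procedure record carries up to **20** diagnostic codes and is abstracted
  weeks later by hospital coders who may already have the biopsy result, so
  a CD-coded procedure record is treated as a CD-indicated endoscopy.

These are the two "endoscopy sources" of the algorithm grid, and modeling
them as independent recording channels (rather than one shared channel) is
what lets the validation distinguish their very different positive
predictive values.

## The algorithm family

`build_algorithm_grid()` enumerates 13 rule variants per channel. All share
the anatomy *scope + contacts*; they differ in the number of required
contacts (1 or 2), the admissible contact types (celiac-coded
gastroenterologist outpatient visit, optionally celiac-coded
hospitalization), a window of 1–5 years, and whether contacts must follow
the scope. Design choices the rule language needed but the source tables do
not fix:

* **Window anchor.** "Two contacts in *k* years" anchors the half-open
  window at the scope date: `[scope, scope + k years)`. This mirrors the
  clinical investigation sequence (biopsy, then follow-up care). The
  alternative — measuring *k* years between the contacts themselves — is a
  defensible reading; it is not the default because it makes the windowed
  rules insensitive to the scope's position in the care pathway.
* **Unwindowed variants** (one contact, or one contact/hospitalization)
  accept contacts anywhere in the study window, before or after the scope.
  The "after the scope" variant must differ from the unordered one-contact
  variant, which forces this reading.
* **Ordering is strict**: a contact on the scope's own day does not count
  as "after" it. The physician visit generating the endoscopy claim and the
  follow-up visit are distinct encounters; same-day duplicates of the same
  claim are deduplicated before counting.
* **Index date** is the earliest scope participating in a qualifying
  pattern, since biopsy defines the diagnosis. A person is counted once no
  matter how many scopes or patterns qualify.

These choices yield provable subset relations (more required contacts can
only shrink the flagged set; wider windows, added event types and dropped
ordering can only grow it), which the test suite checks on randomized
bundles, alongside exact agreement with a brute-force enumerator over every
(scope, contact-subset) combination on small cohorts.

## Accuracy statistics

Sensitivity, specificity, PPV and NPV are binomial proportions over the
labeled cohort; each is reported with the efficient-score (Wilson) interval
**corrected for continuity**. The implementation uses z = 1.96 exactly
rather than the full-precision normal quantile: the difference is below the
two-decimal reporting precision, and the published tables this package
reproduces were evidently computed with 1.96. Reported percentages round
half up (2 dp for full tables, 1 dp for abstract-style summaries).
Predictive values are taken directly from the validation cohort without
prevalence adjustment: when the negative reference is the entire source
population, cohort prevalence *is* population prevalence.

Degenerate cells are explicit: a measure whose denominator is empty (e.g.
PPV when nothing is flagged) is *not applicable*, never zero; a proportion
at 0 or n pins the corresponding interval bound to 0 or 1.

For age-subgroup re-validation (`subgroup_validation()`), positives are
restricted by age at diagnosis. Negatives have no diagnosis date; their age
is measured at the study-window midpoint. That convention is configurable
(`negative_age_on`) because no principled unique choice exists — any fixed
reference date inside the window is defensible, and with multi-year windows
the choice shifts which birth cohorts fall under a cutoff.

Duplicate chart-review agreement uses weighted kappa over the ordered Marsh
grades. The default weighting is quadratic — the common default for ordinal
grades — with linear available; the hand-checked oracle in the tests works
a 3-category table through the defining formula.

## Incidence and trends

`person_years()` accumulates each child's eligible fraction of every
calendar year, splitting exactly at the birthday when it crosses an
age-band boundary, so total person-years equal total eligible time and a
full calendar year contributes exactly 1.0. Age bands default to the 5-year
pediatric bands 0–4/5–9/10–14 (configurable; nothing in the source fixes
the banding) and to single years of age for trend-model denominators.

The directly standardized rate is `dsr = Σ wᵢ dᵢ/nᵢ × 100,000` with
variance `Σ wᵢ² dᵢ/nᵢ² × 100,000²`. Its CI is the Fay–Feuer gamma method,
chosen for validity at the low event counts typical of pediatric CD. The
upper bound uses the max-weight augmentation: with `w_M = max wᵢ/nᵢ`
(per 100,000), `y⁺ = dsr + w_M`, `v⁺ = v + w_M²`, the upper bound is
`v⁺/(2y⁺) · χ²₍₂y⁺²/v⁺₎(1 − α/2)`. In the single-stratum case this
collapses to the exact Poisson chi-square interval, which the tests verify
to a relative 1e-9 — and interval coverage is confirmed conservative
(93–99% across 500 simulated replicates). The bundled
`synthetic_standard_population()` is a uniform stand-in for a census
age–sex profile, which is not redistributable; substitute the real weights
for real analyses.

The trend model is a log-linear Poisson regression of stratum event counts
with a person-years offset: year (continuous, centered at the first study
year so the intercept is interpretable), sex, and age at diagnosis, with
optional year×age interaction and quadratic-year term as the linearity
check. APC = (exp(β_year) − 1) × 100. Wald intervals on exponentiated
coefficients match the symmetric printed intervals of published trend
tables. The fit is delegated to `stats::glm`; the tests additionally verify
the coefficients against an independent gradient-based optimizer of the
same likelihood to 1e-6.

## What the synthetic cohort emulates — and what it does not

`simulate_population()` draws an **open cohort**: the configured
`n_children` comprises children aged 0–14 at window start plus birth
cohorts entering during the window, so every age stratum holds person-time
in every study year (a closed cohort would empty the youngest band as the
study progresses). Each child's case risk is the configured incidence times
their individual at-risk person-time (ages 6 months to <15 years inside the
window); cases then follow the clinical sequence screening visit →
endoscopy → post-diagnosis gastroenterology follow-up, with the two
endoscopy recording channels sampled independently
(`p_ohip_endoscopy_billed`, `p_sds_record_cd_coded`). Non-cases contribute
background endoscopies (both channels, no CD code) and, rarely, CD-coded
visits (`background_cd_code_noise`) — the coding noise that erodes PPV in
the fee-claim channel, e.g. gluten sensitivity without biopsy confirmation,
which has no diagnostic code of its own.

Defaults are the study conditions of the motivating validation setting:
235,320 children ever resident over a 2005–2011 window, incidence 10 per
100,000 at-risk person-years (expected positive reference cohort ≈ 110–115
children). The behavioral probabilities have no published source and are
stated assumptions: endoscopy billed 0.95, procedure record CD-coded 0.85,
post-diagnosis follow-up visit probability 0.9 per year, background
endoscopy 300 per 100,000 PY, CD-code noise 0.001, eligibility gap 0.02.
The default seed is 20110629, always overridable.

Known departures from real data, hence limits on what passing tests show:

* real fee and intervention code dialects are replaced by configurable
  placeholder code sets; only the matching *rules* (prefix matching of the
  CD code family, set membership of endoscopy codes) are faithful;
* visit-frequency distributions are simple Bernoulli/Poisson-per-year
  choices, not fitted to utilization data;
* follow-up is right-censored at the window end, so cases diagnosed late in
  the window have fewer chances at qualifying contacts; with follow-up
  probability below 1 this slightly depresses late-window detection — a
  real phenomenon in windowed administrative studies, but here a modeled
  artifact to keep in mind when interpreting simulated trends
  (parameter-recovery tests therefore pin the follow-up probability to 1);
* the chart-review identification funnel and rater behavior behind the
  reference labels are not simulated — labels are generated directly from
  truth;
* `build_validation_fixture()` places one minimal qualifying (or
  near-missing) event pattern per child, exactly sufficient for the
  requested confusion table; it reproduces published 2×2 tables, not the
  event richness of the cohorts behind them.

## Numerical conventions and test scale

Dates are ISO-8601; eligibility intervals and scope-anchored windows are
half-open `[start, end)`, which makes gap detection and window membership
unambiguous. Calendar arithmetic for "+ k years" rolls February 29 back to
February 28. Rounding for display is half-up. Small-cell suppression
(counts 1–5 shown as `"<6"`, out-of-union counts rounded to the nearest 10)
applies only when rendering reports, never to the statistics themselves.

Test problem sizes are the package's own choices balancing statistical
resolution against runtime: sensitivity-recovery simulations use 200,000
children at an elevated incidence (600 per 100,000 at-risk PY) so that the
±0.02 recovery band is about three binomial standard errors wide — at the
default incidence the reference cohort (~115 cases) is far too small to
resolve 0.02; gamma coverage uses 500 replicates; trend recovery simulates
a 9% annual increase over 17 years of stratum-level counts and requires
recovery within three standard errors.

## Limitations

The package validates *rules over codes*, not clinical truth: its accuracy
statistics are only as good as the reference standard supplied. No
record-linkage or deduplication machinery is included (person identifiers
are assumed pre-linked), no ROC analysis or prevalence-adjusted predictive
values are offered, and real-world code-set dialects must be supplied
through `claims_config()`.
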
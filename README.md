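# celiacclaims

Validation of claims-based case-ascertainment algorithms for biopsy-proven
pediatric celiac disease.

## The problem

Health-administrative databases — physician billing claims, same-day-surgery
procedure records, hospital discharge abstracts — cover whole populations and
are attractive for chronic-disease surveillance. But a diagnostic code on a
claim is not a diagnosis. Before administrative data can be used to count
incident cases of pediatric celiac disease (CD), the code-based rules that
flag "cases" must be validated against a reference standard in which true
disease status is known (biopsy-proven CD: duodenal histology of Marsh grade
IIIa or above).

This package implements that entire validation workflow on linked tabular
claims data, for epidemiologists and health-services researchers:

* **a linked-claims data model** — population registry with coverage
  eligibility intervals, outpatient claims (one diagnostic code each),
  same-day-surgery records (up to 20 diagnostic codes), hospitalizations and
  physician specialties, read and written as plain CSV;
* **a declarative grid of 26 case-ascertainment algorithms**, all of the form
  *endoscopy ("scope") + celiac-coded health-system contacts*, crossed over
  two endoscopy recording channels that differ in coding behavior: the
  outpatient **fee claim** (billed at procedure time, any indication) and the
  **procedure record** (abstracted later by coders who may already know the
  biopsy result, so it can carry the CD code);
* **diagnostic accuracy statistics**: sensitivity, specificity, PPV and NPV
  with 95% CIs by the efficient-score (Wilson) method corrected for
  continuity, age-subgroup re-validation, and weighted kappa for duplicate
  chart-review agreement;
* **incidence estimation**: exact person-years, direct age–sex
  standardization with Fay–Feuer Gamma-method CIs, and Poisson regression
  (person-years offset) for the annual percent change
  APC = (exp(β_year) − 1) × 100;
* **a synthetic-cohort generator** with known ground truth, which both powers
  the property tests and reconstructs published validation tables exactly
  from their printed statistics.

For a proportion x/n with p = x/n and z = 1.96, the continuity-corrected
score interval used throughout is

```
L = [2np + z² − 1 − z·sqrt(z² − 2 − 1/n + 4p(n(1−p)+1))] / [2(n + z²)]
U = [2np + z² + 1 + z·sqrt(z² + 2 − 1/n + 4p(n(1−p)−1))] / [2(n + z²)]
```

clamped to [0, 1], with L = 0 when x = 0 and U = 1 when x = n.

## Worked example

Rebuild the fee-claim-channel validation cohort from its four confusion-table
cells, re-run the algorithm, and recompute its operating characteristics:

```r
library(celiacclaims)

fx <- build_validation_fixture(81, 71, 34, 235249, "13-OHIP")
res <- apply_algorithm(fx$bundle, "13-OHIP")
confusion_table(res, fx$bundle$labels)
#>      tp    fp    fn     tn
#>      81    71    34 235249
render_table1(operating_characteristics(confusion_table(res, fx$bundle$labels)))
#>   algorithm_id sensitivity         specificity         ppv                 npv
#>   13-OHIP      70.43 (61.09–78.39) 99.97 (99.96–99.98) 53.29 (45.05–61.36) 99.99 (99.98–99.99)
```

The sensitivity cell reads: of 115 children with biopsy-proven CD, the
algorithm (an endoscopy fee claim plus at least one celiac-coded
gastroenterologist visit after it) flagged 81, i.e. 70.43%, with a 95%
continuity-corrected score CI of 61.09–78.39%. The PPV cell shows the
population-based penalty of an indication-blind endoscopy code: barely half
of flagged children truly have CD.

Simulated surveillance on a synthetic cohort:

```r
sim <- simulate_population(sim_params(n_children = 20000,
                                      annual_incidence_per_100k = 150,
                                      seed = 42))
r1 <- apply_algorithm(sim$bundle, "13-OHIP")
r2 <- apply_algorithm(sim$bundle, "1-SDS")
overlap(r1, r2)
#>   only_a  both only_b
#>       14   101      6

den <- person_years(sim$bundle$registry, sim$bundle$eligibility,
                    as.Date(c("2005-01-01", "2011-12-31")))
incidence_series(r2, sim$bundle$registry, den, synthetic_standard_population())
#>    year   dsr conf.low conf.high events
#>    2005 178.     114.       265.     24
#>    2006 119.      68.0      193.     16
#>    ...
autoplot(incidence_series(r2, sim$bundle$registry, den,
                          synthetic_standard_population()))
```

Each `dsr` is the age–sex standardized rate per 100,000 person-years with
its Gamma-method CI; the overlap row is the Venn partition of children
flagged by the two recording channels. `fit_poisson_trend()` then estimates
the annual percent change from the same case records, and `run_pipeline()`
chains all stages (simulate → ascertain → validate → incidence → trend) into
reproducible CSV/JSON reports with small-cell suppression.

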
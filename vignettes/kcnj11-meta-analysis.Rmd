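---
title: "Methods: meta-analysis of a biallelic risk variant with gamet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of a biallelic risk variant with gamet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamet)
library(dplyr)
```

gamet implements the complete statistical pipeline of a genetic-association
meta-analysis for a biallelic variant, organised around the KCNJ11 E23K
polymorphism (rs5219) and type 2 diabetes: 48 published studies — 56,349
cases, 81,800 controls and 483 family trios — whose summary table ships with
the package as `kcnj11_table1()`. This vignette is the package's account of
the statistical model behind each stage, the defaults and why they were
chosen, what the synthetic-data generator does and does not emulate, and the
known limitations of reconstructing an analysis from a printed summary
table.

## The data model

Each study is one row: arm sizes, the risk (23K) allele frequency per arm,
and optionally per-arm genotype counts (EE/EK/KK), trio transmission counts,
and covariates. Three designs occur: `population` (case-control),
`family` (trio/TDT) and `both`. The packaged table carries the published
values verbatim, including a nominally "minor" allele frequency of 0.69
(the label is nominal; the column is the risk-allele frequency) and two
control frequencies of 0.61 that sit far from every neighbouring estimate
and are plausibly transcription errors in the source table. They are kept
as printed: the fixture's job is to reproduce its source, and the
sensitivity machinery (leave-one-out) is the right tool for asking how much
they matter.

## Per-study effect sizes

**Allele contrast.** Published study tables rarely include allele counts,
so `allele_table_from_maf()` reconstructs them: `a = round(2 N maf)` risk
alleles among cases (half-values round away from zero) and the complement
`2N - a` in the other cell, so each arm contributes exactly `2N` alleles.
Treating the two alleles per individual as independent is the standard
allele-contrast convention; it ignores within-individual correlation, which
is small near Hardy-Weinberg equilibrium. The log odds ratio and its Woolf
variance are

$$\hat\theta = \log\frac{ad}{bc}, \qquad
  v = \tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d .$$

**Continuity correction.** When any cell is zero, 0.5 is added to all four
cells (Haldane–Anscombe) — only then, never otherwise. No study in the
packaged table triggers it after reconstruction, so desk results are
insensitive to this choice; it exists for simulated and user data.

**Genotype models.** Where genotype counts exist, `genotype_table()` forms
the heterozygous (EK vs EE), homozygous (KK vs EE), dominant (EK+KK vs EE)
and recessive (KK vs EE+EK) contrasts. The packaged table does not print
per-study genotype counts, so on it these four models are reported as
unavailable; they are exercised end to end on simulated tables. The
alternative — imputing genotype counts from the allele frequency under HWE
— was rejected for the fixture because it would manufacture data the
printed table does not contain.

**HWE.** `hwe_test()` is the 1-df chi-square against the proportions
implied by the sample's own allele frequency, not the exact test: the
printed quality-control column mostly reports thresholds ("> 0.05"), and
the chi-square is exactly reproducible. A monomorphic sample is defined to
be in equilibrium (`chi2 = 0, p = 1`).

## Pooling

Fixed-effect weights are `w_i = 1/v_i`; Cochran's
`Q = sum w_i (y_i - \bar y_w)^2` and `I^2 = max(0, (Q - df)/Q)`.
`pool_dl()` adds the DerSimonian–Laird moments estimator

$$\hat\tau^2 = \max\!\left(0,\;
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

then re-weights by `1/(v_i + tau2)`. When `Q <= k - 1` the estimator
truncates and the result coincides bitwise with the fixed-effect pool — a
property the test suite asserts. All 95% intervals use the exact normal
quantile 1.959964, which the reproduced tables imply, rather than 2. No
iterative (REML/Paule–Mandel) estimator is offered: the whole pipeline is
closed-form and deterministic by design.

**Subgroups.** `pool_subgroups()` pools each stratum by DL and tests
between-stratum heterogeneity with
`Q_between = sum W_g (theta_g - theta_bar)^2` on `G - 1` df, where `W_g`
uses the *random-effects* stratum standard errors (the mixed-effects
convention; the source analysis does not state which convention it used).
Two mapping decisions are exposed rather than buried:

* The one study labelled "Chinese" is, by default, assigned to no ethnic
  stratum, because the reported stratified analysis counts 14 East Asian
  studies, which excludes it. `ethnicity_group(..., "east_asian")` folds it
  in explicitly, and the report accepts `map_chinese_to = "east_asian"`.
* The sample-size stratification uses the stated rule, cases ≥ 1000
  (`size_group()`, threshold configurable). On the packaged table this
  yields 19 "Large" studies; the reported stratum counts (22/26) cannot be
  reproduced by any single threshold rule we tried (a total-N ≥ 2000 rule
  gives 23), so the stated rule was kept and the discrepancy is documented
  here rather than tuned away.

**Sensitivity.** `leave_one_out()` re-pools after dropping each study in
turn. On the packaged table, all 47 exclusions leave the pooled OR between
1.088 and 1.122 — no single study, including the two suspect rows, flips
the direction of the pooled effect.

## Family-based studies and cross-design combination

The TDT odds ratio is the ratio of transmitted to untransmitted risk
alleles from heterozygous parents, with variance `1/T + 1/U` — robust to
population stratification because each trio is its own control.
`combine_designs()` uses the two-stage form: each design pooled by DL,
the two design-level estimates combined by inverse variance, with a 1-df
Q for cross-design consistency. The alternative one-stage form (entering
TDT estimates as ordinary studies in a single DL pool) is not recoverable
from the published description; the two-stage form was chosen because it
keeps the design-level heterogeneity separate and reduces to the one-stage
answer when both designs are internally homogeneous (asserted in the
tests). The two published trio studies print only trio counts, not T/U, so
TDT operations run on simulated trios; the published pooled TDT OR of 0.87
is a non-reproducible reference, not a test target.

## Meta-regression and small-study bias

`meta_regress()` is weighted least squares of `y` on a moderator design
matrix with the moments estimator of residual heterogeneity applied once
(fit with fixed-effect weights, estimate `tau2_res` from the weighted
residual sum of squares with the trace correction, refit with
`1/(v + tau2_res)`). The proportion of heterogeneity explained is
`1 - tau2_res / tau2_null`, clamped to [0, 1], with `tau2_null` from the
intercept-only model — which reproduces `pool_dl()` exactly, a tested
invariant. Coefficient tests are Wald-normal. The published covariates
(per-study mean BMI, age, sex) are not printed per study, so the reported
"BMI explains ~11% of heterogeneity" figure is demonstrable only on
synthetic data; the machinery is calibrated there instead (below).

`egger_test()` is the classical unweighted form: OLS of the standardised
effect on precision, intercept tested on `k - 2` df. Worth knowing: for
odds ratios the test has intrinsically inflated type-I error when the
common effect is far from the null, because the log OR and its Woolf
standard error are correlated — a property of the test, not of any
implementation. The calibration study in the test suite therefore runs at
the natural null for a bias test (true OR 1, no heterogeneity, no
selection, 30 studies of 100–2000 per arm), where the rejection rate over
1000 replicates must land in 5% ± 2%.

## Translation: PAR and power

Population attributable risk uses the classical approximation
`PAR = (OR - 1)/OR × RAF`. The published PAR percentages (4.6% overall)
are not derivable from any printed (OR, RAF) pair via this formula —
(1.12 − 1)/1.12 × 0.40 = 4.3% — so PAR is reported as computed from the
package's own pooled OR and weighted control frequency, and no test
asserts the printed percentages.

`sample_size_for_power()` is the closed-form two-proportion normal
approximation on allele counts (two independent alleles per individual,
equal arms): with `p1 = p0·OR/(1 − p0 + p0·OR)`,

$$m \;=\; \frac{(z_{1-\alpha/2} + z_{\beta})^2\,
  \bigl(p_0(1-p_0) + p_1(1-p_1)\bigr)}{(p_1 - p_0)^2}$$

alleles per group, `n = ceiling(m/2)` individuals, presented to the
nearest hundred. With the published stratum summaries (OR 1.12 at
frequency 0.40; OR 1.13 at 0.36) this reproduces the published 2500 and
2200 case-control pairs. In `run_full_analysis()` the inputs are the
recomputed stratum OR and weighted control frequency, each rounded to two
decimals first — the precision at which such summary inputs are
conventionally quoted; this is an input convention, not presentation
rounding, which lives only in `write_report()`.

## The synthetic-study generator

`simulate_studies()` draws, per study: a true log OR from
`Normal(mu, tau2)`; a control risk-allele frequency from
`Beta(raf_alpha, raf_beta)`; per-arm sizes log-uniform; control genotypes
multinomial under HWE; case genotypes multinomial with genotype weights
`1 : OR : OR²` times the control proportions, renormalised — the exact
per-allele odds model rather than rejection sampling, so generation is
deterministic and fast. Reported frequencies are computed from the sampled
counts, so generated tables always satisfy the schema's internal
consistency checks. Family studies draw heterozygous-parent transmissions
`H ~ Binomial(2·n_trios, 2p(1−p))` and `T ~ Binomial(H, logistic(theta))`
— a simplification that treats transmissions as exchangeable rather than
simulating parental genotypes.

Defaults emulate the packaged collection: 46 case-control plus 2 trio
studies, true OR 1.12, `tau2 = 0.04` (the heterogeneity the packaged table
itself shows), control frequencies Beta(8, 13) (mean 0.38, spanning the
observed 0.07–0.61 with low probability in the tails), arm sizes 100 to
10,000. Each study has its own sub-stream (per-study seeds drawn once from
the configuration seed), so study `i`'s data are invariant to the
collection size — convenient for debugging — and identical configurations
give byte-identical tables.

What the generator does **not** emulate: linkage disequilibrium with a
causal variant, covariate-dependent allele frequencies, genotyping error,
or departures from HWE in controls. Passing calibration tests therefore
shows the estimators are correct under the stated sampling model, not that
real collections satisfy that model. `simulate_with_covariate()` splits
`tau2` between a standard-normal study-level covariate and residual
heterogeneity (`beta² = f·tau2`), supporting the proportion-explained
calibration; `selection_bias` suppresses small non-significant studies to
emulate publication bias for the Egger machinery.

## Calibration study sizes

The test suite's simulation studies use: 1000 replicates of k = 30 for the
Egger type-I rate; 500 replicates of k = 200 (true OR 1.12, tau2 = 0.02)
for DL interval coverage, required ≥ 93%; 500 replicates of k = 100
(half the heterogeneity covariate-driven) for proportion-explained
recovery within ±0.15. These sizes give Monte-Carlo standard errors
comfortably below the tolerances they are checked against (e.g. ±0.7
percentage points on a 5% rejection rate at 1000 replicates) while keeping
the whole suite under a minute of simulation time on one core.

## Known limitations

* Allele tables are reconstructed from two-decimal frequencies, not the
  original genotype counts: the pooled allele OR on the packaged table
  (1.096, 95% CI 1.029–1.168) is close to, but not identical with, the
  published 1.12 (1.09–1.16) — reconstruction rounding plus the two
  suspect 0.61 control frequencies fully account for the gap, and the
  leave-one-out range shows no qualitative sensitivity. (The published
  abstract and results sections themselves disagree on the overall CI's
  second decimal.)
* Genotype-based models, BMI stratification, meta-regression on real
  covariates and TDT pooling are unavailable on the packaged table because
  the per-study inputs were never printed; all are fully exercised on
  simulated tables.
* No multiple-testing adjustment is applied across subgroup analyses,
  matching the reproduced analysis; interpret stratum p-values
  accordingly.
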
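# gamet — genetic association meta-analysis toolkit

gamet implements the statistical pipeline used to synthesise published
case-control and family-based association studies of a biallelic variant,
built around the KCNJ11 E23K polymorphism (rs5219) and type 2 diabetes.
The gene encodes the Kir6.2 subunit of the pancreatic ATP-sensitive
potassium channel; whether the 23K allele modestly raises diabetes risk
was settled by pooling dozens of association studies, and this package
re-implements that entire analysis as reusable, tested R functions. It is
aimed at genetic epidemiologists who have a per-study summary table (arm
sizes, allele frequencies, optionally genotype or trio counts) and want
the full battery: per-study odds ratios under five genetic models,
random-effects pooling, heterogeneity decomposition, stratified and
sensitivity analyses, cross-design combination with transmission
disequilibrium tests, small-study bias diagnostics, meta-regression, and
the translational quantities (attributable risk, power).

## The model

Per study, the allele-contrast log odds ratio and Woolf variance are

    theta_i = log(a d / (b c)),   v_i = 1/a + 1/b + 1/c + 1/d

with allele counts reconstructed from the reported frequencies
(`a = round(2 N maf)`, arm totals conserved). Pooling is
DerSimonian–Laird random effects: with fixed-effect weights `w_i = 1/v_i`
and Cochran's `Q`,

    tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))

and the pooled estimate re-weights by `1/(v_i + tau2)`;
`I2 = max(0, (Q - df)/Q)`. Subgroups add a between-stratum
`Q_b = sum W_g (theta_g - theta_bar)^2` on `G - 1` df. Trio studies enter
through the TDT odds ratio `T/U` (transmitted vs untransmitted risk
alleles, variance `1/T + 1/U`) and are combined with the case-control pool
by two-stage inverse variance. Meta-regression uses the method-of-moments
residual-heterogeneity estimator; Egger's test regresses the standardised
effect on precision. Attributable risk is `(OR-1)/OR * RAF`; sample sizes
come from the two-proportion normal approximation on allele counts. The
48-study summary table (56,349 cases, 81,800 controls, 483 trios) ships as
a packaged fixture, and `simulate_studies()` generates collections with
known true OR and heterogeneity for calibration.

## Worked example

```r
library(gamet)
library(dplyr)

studies <- kcnj11_table1()
summarize_studies(studies)
#> # A tibble: 1 × 5
#>   n_studies total_cases total_controls total_trios ethnicity_counts
#>       <int>       <int>          <int>       <int> <list>
#> 1        48       56349          81800         483 <spc_tbl_ [5 × 2]>

studies |> effect_sizes("allele") |> pool_dl()
#> Random (DerSimonian-Laird)-effect pool of 47 studies
#>   OR 1.096 (95% CI 1.029-1.168), Z = 2.85, p = 0.00443
#>   Q = 578.85 on 46 df (p = 2.76e-93), tau2 = 0.0401, I2 = 92.1%
```

The pooled per-allele OR of 1.096 says carrying one extra 23K allele
multiplies the odds of type 2 diabetes by about 1.10 (the published
estimate from the original genotype counts is 1.12; reconstruction from
two-decimal frequencies accounts for the difference). `I2 = 92%` flags
substantial between-study heterogeneity, so the random-effects model and
the stratified analyses are the relevant ones:

```r
studies |>
  effect_sizes("allele") |>
  mutate(group = ethnicity_group(ethnicity)) |>
  pool_subgroups(group) |>
  tidy() |>
  select(level, k, or, ci_low, ci_high)
#> # A tibble: 4 × 5
#>   level          k    or ci_low ci_high
#> 1 Caucasian     20 1.10   1.02     1.19
#> 2 East Asian    14 1.16   1.10     1.21
#> 3 Other          7 0.968  0.617    1.52
#> 4 Indian         5 1.03   0.851    1.25

egger_test(effect_sizes(studies, "allele"))$p   # 0.815 — no small-study bias
sample_size_for_power(p0 = 0.40, or = 1.12)$n_presented   # 2500 pairs
attributable_risk(or = 1.12, raf = 0.40)        # 0.0429
```

The risk is detectable in Caucasians and East Asians but not in the
smaller Indian and "Other" strata; a future study powered at 80% for the
Caucasian effect needs about 2500 case-control pairs; and roughly 4% of
disease in a population with allele frequency 0.40 is attributable to the
variant. `run_full_analysis(studies)` executes every stage at once and
`write_report()` exports TSV/JSON bundles; `autoplot()` draws forest and
funnel plots.

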
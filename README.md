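# eaccd

Data-driven prognostic staging for censored survival data. The package is
aimed at biostatisticians working with registry-style case listings
(factors such as TNM category, age group, histology; survival in months;
a cause-specific death indicator) who want to *learn* an ordered staging
system from the data instead of curating one by committee — and to compare
the learned system against AJCC 8th-edition lung staging.

## Method in brief

Patients sharing one level of each active factor form a **combination
cohort** (e.g. `T1bN1M0A0H1`). The pipeline then:

1. **Initial dissimilarity** — for cohorts *i, j*, the Mann–Whitney
   probability θ = P(X_i < X_j) is estimated by Kaplan–Meier plug-in
   (∫ Ŝ_j dF̂_i up to the common follow-up limit, half weight on ties and
   on the joint residual tail), symmetrized so θ(i,j) + θ(j,i) = 1, and
   mapped to d = 2|θ − ½| ∈ [0, 1].
2. **Ensemble learning** — B runs of two-phase PAM (BUILD + SWAP) with the
   cluster count k drawn uniformly from a range; the learned dissimilarity
   δ(i,j) is the fraction of runs separating i and j.
3. **Minimax linkage** — agglomerative clustering of δ merging the pair
   whose union has the smallest prototype radius
   min_c max_x δ(c, x); every cluster carries its prototype combination.
4. **Cut at the knee** — for each candidate group count k, groups are
   ordered by decreasing five-year KM survival and scored 1..k; Harrell's
   C-index traces a curve over k, and n\* is the smallest k after which
   marginal gains fall below 5% of the curve's span (manual override
   available).
5. **Comparison** — AJCC 8th-edition stages (bundled lookup fixture),
   stage-by-group contingency table, midrank Spearman correlation computed
   from counts, and a correlated C-index difference test using the joint
   influence-function variance.

A synthetic registry generator (exponential/Weibull survival over factor
combinations, administrative censoring over 60–96 months, integer month
times, optional planted prognostic tiers) makes every stage testable
without access to any real registry.

## Worked example

Thirty combinations with three planted hazard tiers (ratio 3), 500
patients each, censored administratively at 60–96 months:

```r
library(eaccd)
sim <- generate_cases(planted_tiers_config(seed = 42))
fit <- run_fit(sim$cases, active_factors = c("T", "N", "M"),
               min_cases = 50, B = 200, seed = 42, ks = 1:8)
fit
#> EACCD fit: 30 combinations, 3 prognostic groups, C-index 0.7113

round(setNames(fit$curve$c_index, fit$curve$k), 4)
#>      1      2      3      4      5      6      7      8
#> 0.5000 0.6624 0.7113 0.7134 0.7147 0.7152 0.7156 0.7163

fit$system$five_year_rates
#>      1      2      3
#> 0.7358 0.3992 0.0694
```

The C-index curve jumps to k = 3 and flattens, so the knee rule picks
three groups — exactly the planted tiers (adjusted Rand index 1 against
truth). Five-year survival drops from 74% in group 1 to 7% in group 3:
risk increases with group number, as a staging system requires. Comparing
the fitted system with AJCC staging on the same patients:

```r
run_compare(fit, sim$cases)
#> Stage/group agreement (midrank Spearman): 0.0177
#> C_a = 0.7113, C_b = 0.5027, delta = 0.2086 (95% CI 0.2014 to 0.2158), p = 0
```

Here the planted tiers were deliberately interleaved against the TNM
ordering, so anatomic stage carries no signal (C ≈ 0.5) while the learned
grouping recovers the truth — the comparison machinery reports exactly
that. On data whose risk follows the factors (the generator's default
effects), the same comparison instead shows a high stage/group correlation
with a small positive delta.

The bundled published 10×11 stage-by-group table is available as a worked
fixture:

```r
spearman_from_contingency(table2_fixture())
#> [1] 0.9618107
#> attr(,"p_value")
#> [1] 0
```

A thin command-line wrapper over the same functions lives in
`inst/scripts/eaccd-cli.R` (`simulate`, `fit`, `compare` subcommands).

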
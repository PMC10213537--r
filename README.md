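# manuremeta

Meta-analysis of paired field-trial comparisons between synthetic-N-only
fertilization (NPK) and partial or full replacement of synthetic N with
animal manure at equal total N input (NPKM), for wheat, maize and rice.
The package is for agronomists and synthesists who have (or want to
simulate) a flat database of such comparisons — arm means, SDs and
replicate counts for grain yield and/or nitrogen use efficiency (NUE),
plus management, climate and soil moderators — and need the full
synthesis pipeline: effect sizes, pooled estimates with confidence
intervals, subgroup analyses, moderator importance, and dose–response
optima.

## The model

Each comparison contributes a log response ratio and its sampling
variance

```
RR = ln(x̄_NPKM / x̄_NPK)
v  = SD²_NPKM / (n_NPKM · x̄²_NPKM) + SD²_NPK / (n_NPK · x̄²_NPK)
```

and groups are pooled by inverse-variance weighting (w = 1/v):

```
RR++ = Σ w·RR / Σ w,   SE = √(1/Σ w),   CI₉₅ = RR++ ± 1.96·SE
```

with percent change `(e^RR++ − 1) × 100 %`; an effect is significant
when the CI excludes zero. Subgroup analysis pools within conventional
bins of each moderator (N rate, substitution rate, climate type,
rainfall, temperature, sunshine, frost-free period, soil organic
matter, total N, alkali N, available P/K, pH). A regression random
forest ranks moderators by permutation %IncMSE, and the top moderators
are fitted as linear/quadratic response curves from which the optimal
substitution rate (vertex) and the minimum N rate for a positive effect
(upward zero crossing) are extracted. A synthetic database generator
with known ground truth makes every stage testable; see
`vignettes/methods.Rmd` for the full methodological account.

## Worked example

```r
library(manuremeta)

# a literature-style database of 400 comparisons with known truth
gen <- generate_database(synthetic_config(n_comparisons = 400, seed = 2024))
rep <- analyze_database(gen$database, analysis_config(seed = 2024))
rep
#> <meta_report> 400 comparisons, crops: wheat/maize/rice, outcomes: yield/NUE, seed 2024
#> Overall pooled effects (percent change, 95% CI):
#>   wheat  yield   +3.8% (+2.5, +5.2) k=56 *
#>   wheat  NUE     +6.9% (+5.0, +8.8) k=41 *
#>   maize  yield   +3.1% (+2.0, +4.1) k=71 *
#>   maize  NUE    +11.0% (+9.9, +12.2) k=88 *
#>   rice   yield   +4.1% (+3.0, +5.3) k=85 *
#>   rice   NUE    +10.1% (+8.6, +11.6) k=59 *
```

Each line is a crop–outcome stratum: the pooled percent change of the
manure-substitution treatment relative to the NPK control, its 95% CI,
the number of comparisons pooled, and `*` when the CI excludes zero.
The generator's default true ratios are 1.033–1.039 (yield) and
1.063–1.100 (NUE), so the pooled estimates above recover the built-in
truth within sampling error.

Subgroup analysis of one moderator:

```r
eff <- effect_sizes(gen$database)
subgroup_analysis(eff, "substitution_rate", outcome = "yield")
#> # A tibble: 4 × 7
#>   variable          bin         k pct_change pct_ci_low pct_ci_high significant
#> 1 substitution_rate overall   212       3.62       2.94        4.30 TRUE
#> 2 substitution_rate <=30       44       4.67       3.10        6.25 TRUE
#> 3 substitution_rate 30-60      77       3.61       2.57        4.65 TRUE
#> 4 substitution_rate >60        91       3.12       2.03        4.21 TRUE
autoplot(subgroup_analysis(eff, "substitution_rate", outcome = "yield"))
```

Dose–response optima from a fixture whose truth is concave in the
substitution rate (vertex 44 %, peak log effect 0.056):

```r
dr  <- make_fixture("dose_response", seed = 42)
cur <- fit_response_curve(effect_sizes(dr$database), "substitution_rate",
                          outcome = "yield")
cur$optimum_x                                     # 43.99
percent_change(predict_curve(cur, cur$optimum_x)) # 5.80 (% yield gain at optimum)
```

Reading a real database is `read_database("db.csv")` (schema in
`db_schema()` and `inst/extdata/db_schema.csv`); rows violating the
validation rules (≥3 replicates, positive means, substitution rate in
(0, 100]) are rejected with reason codes, never silently dropped.

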
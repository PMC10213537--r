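---
title: "Methods: pooling manure-substitution field trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling manure-substitution field trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manuremeta)
```

## The question and the data

Replacing part or all of the synthetic nitrogen in a fertilization plan
with animal manure — at **equal total N input** — is a widely used
strategy to cut synthetic-N use in wheat, maize and rice systems. Its
effect on grain yield and on nitrogen use efficiency (NUE) varies across
trials, so a quantitative synthesis pools many paired comparisons, each
contrasting a synthetic-only control (NPK) with a manure-substitution
treatment (NPKM) from the same experiment.

The unit of analysis is a *comparison*: one row holding the NPK and NPKM
arm means, standard deviations and replicate counts (at least three
replicates per arm) for one crop and outcome, plus moderators describing
management (total N rate, manure substitution rate), climate (climate
type, rainfall, temperature, sunshine, frost-free period) and topsoil
properties (organic matter, total N, alkali-hydrolysable N, available P
and K, pH). NUE, where not reported directly, is derived from aboveground
N uptake as the apparent recovery `(N_t - N_0) / F_t x 100%`; negative
derived values are retained and flagged, because discarding them would
bias the pooled NUE upward. Several comparisons may come from one study;
each is treated as an independent observation, which matches how such
databases are pooled in practice but understates between-comparison
correlation within long-term trials — a documented assumption, not a
modelling claim.

## Effect size and pooling model

For each comparison the effect size is the log response ratio

$$RR = \ln\!\left(\bar{X}_{NPKM} / \bar{X}_{NPK}\right),$$

so a positive value means manure substitution increased the outcome, and
`(e^{RR} - 1) \times 100` is the percent change against the control.
Its sampling variance is the delta-method plug-in

$$v = \frac{SD_{NPKM}^2}{n_{NPKM}\,\bar{X}_{NPKM}^2}
    + \frac{SD_{NPK}^2}{n_{NPK}\,\bar{X}_{NPK}^2},$$

which depends on the data only through each arm's CV² / n — hence the
scale invariance and arm-swap antisymmetry the tests enforce. Groups are
pooled by inverse-variance weighting, \(w = 1/v\):

$$RR_{++} = \frac{\sum w\,RR}{\sum w}, \qquad
  SE = \sqrt{1 / \textstyle\sum w}, \qquad
  CI_{95} = RR_{++} \pm 1.96\,SE,$$

and an effect is called significant exactly when the CI excludes zero.
These are fixed-effect weights; a DerSimonian–Laird random-effects option
(method-of-moments between-study variance added to each \(v\)) is
available behind `model = "random"` for sensitivity analysis, not as the
default, so that the default reproduces the printed estimator exactly.

Two further numerical choices:

* **Missing SDs.** Studies often omit arm SDs. The default imputes
  `SD = 0.10 x mean` (a typical field-trial CV); an `"average-cv"` policy
  uses the mean CV of SD-complete records in the same crop–outcome
  stratum. Imputed rows are flagged; sensitivity reruns at CV 0.05/0.15
  are one argument away.
* **Zero variance.** A comparison reporting `SD = 0` in both arms would
  receive infinite weight; its variance is floored at `1e-6` and flagged.

Bootstrap confidence intervals (bias-corrected percentile over
comparisons, 4999 resamples by default, seeded) are offered as an
alternative to the parametric CI. The two agree for homogeneous groups;
when effects vary systematically with a moderator the bootstrap interval
is *wider* than the parametric one, because resampling sees the real
heterogeneity that the plug-in SE ignores. That divergence is a feature
of the data, not a defect of either interval.

No multiplicity adjustment is applied across the many subgroup tests (the
report header says so prominently); with fourteen moderators and two
outcomes per crop, isolated significant bins are expected by chance.

## Subgroup analysis and binning

Each moderator is split into the conventional bins (N rate
≤120 / 120–240 / 240–360 / >360 kg N ha⁻¹; substitution rate
≤30 / 30–60 / >60 %; soil-nutrient bins following the Chinese second
soil survey classification; pH ≤5.5 / 5.5–6.5 / 6.5–7.5 / >7.5; and so
on). All intervals are lower-open/upper-closed `(a, b]` — the only
convention consistent with labels like "≤120" — so a boundary value
belongs to the lower bin. Binning is a partition: property tests assert
that every finite value maps to exactly one label across all twelve
numeric schemes. Missing moderator values map to `"unknown"` and drop
out of that subgroup analysis only; they are never imputed, and the
record still contributes to the overall pooled effect. Because the
fixed-effect estimator is linear in weights, pooling all comparisons at
once equals pooling the per-bin estimates weighted by their total
weights, to machine precision — the suite checks this composition
identity at `1e-12`.

## Moderator importance and dose–response curves

A regression random forest of per-comparison `rr` on the moderators
ranks their importance by permutation %IncMSE: the raw out-of-bag MSE
increase after permuting one moderator, averaged over trees, expressed
as a percentage of the baseline OOB MSE. (The other convention in
circulation scales by the bootstrap SD of the increase; the normalisation
used here is stated in the result's metadata.) Defaults are 500 trees,
`mtry = ceiling(p/3)`, integer-coded categorical moderators (one-hot as
an option) and an explicit seed; runs are bit-reproducible given seed
and row order. Moderators missing in more than half the rows are
excluded with a warning; remaining rows enter complete-case.

The top-ranked continuous moderators are then fitted against `rr` by
ordinary least squares, linear and quadratic. `form = "auto"` keeps the
quadratic only when its AIC beats the linear fit by more than 2 (the
usual indistinguishability margin), and prefers the linear model
outright when it is already numerically perfect — plain smaller-AIC is
ill-defined when both fits have round-off residuals. Curves are called
significant at p < 0.01 (model F-test). From a fitted curve the package
extracts:

* the **optimum** — the vertex `-b/(2c)` of a concave quadratic,
  reported only inside the observed moderator range (a vertex beyond it
  is a boundary note, not an estimate);
* the **threshold** — the smallest upward zero crossing inside the
  range, e.g. the minimum total N rate above which substitution helps
  NUE; multiple sign changes trigger a warning and the smallest upward
  crossing is returned.

Fits are unweighted, matching how such response curves are usually drawn
over all crops jointly; per-crop fits are one `crop =` argument away.

## The synthetic generator: what it emulates, and what it does not

No comparison database of this kind is publicly deposited, so the
package ships a generator whose defaults *are* the study conditions the
pipeline is meant to face: crop mix 23/40/37% wheat/maize/rice
(proportional to published study counts), baseline NPK yields of
5.21/8.59/7.23 t ha⁻¹ and NUE of 33.6/34.5/28.8%, true effect ratios of
1.033/1.038/1.039 (yield) and 1.063/1.100/1.092 (NUE), between-study SD
0.05 on the log scale, within-arm CV 0.08, 3–4 replicates per arm, 15%
of rows with SDs withheld, and moderator distributions spanning all the
subgroup bins (with climate variables correlated with crop: rice sites
are wetter, warmer, mostly subtropical monsoon). The study-to-study
spread of baselines (lognormal CV 0.15) reflects the variety of sites;
where no published value pins a parameter down, the default is a single
realistic choice stated here and not revisited.

For each comparison the generator samples moderators, draws the
study-level log effect `theta = ln(true_ratio(moderators)) + N(0, sd)`,
sets true arm means `(baseline, baseline * e^theta)`, and produces
observed summaries in one of two modes:

* `sd_mode = "replicates"` (default): lognormal replicate draws per arm;
  the observed mean and SD are the sample statistics. This exercises the
  estimator's *plug-in* behaviour — variance estimates with only 2–3
  degrees of freedom, exactly as in real 3–4-replicate trials.
* `sd_mode = "normal"`: the observed mean is drawn from its sampling
  distribution and the true SD is reported — the correctly specified
  regime in which the parametric CI has its nominal properties.

The distinction matters. Under replicate-estimated SDs the weights
`1/v̂` are heavy-tailed (a lucky pair of small sample SDs earns a huge
weight), and Monte Carlo shows the nominal 95% CI then covers the truth
in only about 70% of null databases, with the pooled point estimate
remaining essentially unbiased. This is a real property of plug-in
inverse-variance pooling at three replicates — present in the published
estimator itself, not an artefact of the generator — and it is why the
calibration and parameter-recovery checks run in the correctly specified
mode, while the default mode keeps the realistic noisy-SD behaviour for
everything else. Users synthesising real 3-replicate data should read
the parametric CI as approximate and consider the bootstrap option.

What the generator does **not** emulate: the geography of real sites,
covariance among moderators beyond the crop–climate link, publication
bias, or correlated multi-year comparisons from one trial. Passing tests
therefore demonstrate that the estimators recover known truth under the
stated sampling model — not that any particular real-world database
satisfies that model.

Four canned fixtures drive validation: `tiny` (6 hand-checkable rows),
`null` (no effect, correctly specified — the CI-calibration reference),
`dose_response` (yield effect concave in substitution rate with vertex
44% and amplitude 0.056; NUE effect linear in N rate crossing zero at
161 kg ha⁻¹; noise SD 10% of each curve's amplitude; N rates sampled on
61–261 kg ha⁻¹ so trials bracket the threshold), and `importance` (one
signal moderator among independent noise). A design-stage power check
fixed these noise levels so the stated recovery tolerances (vertex
±0.5, threshold ±2 at n = 300) are attainable with comfortable margin.

## Problem sizes and determinism

The shipped validation uses 1,000 null databases of 60 comparisons for
CI calibration, k = 1,000 comparisons for constant-effect recovery,
n = 300 per dose–response fixture arm, and 20 seeded forests of 500
trees for the importance ranking — sizes at which Monte Carlo error is
small relative to every tolerance while a full run stays interactive.
Every stochastic step takes an explicit seed, and the analysis bundle
(`analyze_database()` + `write_report_bundle()`) is byte-identical
across runs for a fixed input and seed; the run manifest records the
seed, configuration, package version and row counts.

## Known limitations

* Comparisons are pooled as independent even when they share a study; an
  aggregate-within-study sensitivity can be emulated by averaging rows
  per study before `effect_sizes()`, but is not a default.
* The parametric CI undercoverages under replicate-estimated SDs (see
  above); this is inherent to the plug-in weights at n = 3–4.
* No small-sample bias correction is applied to the log response ratio.
* Moderator interactions are not modelled; importance and curves treat
  moderators one at a time.
* Heterogeneity decomposition (Q statistics) is not part of the
  reporting surface.
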
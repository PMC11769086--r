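---
title: "Dual lake-health evaluation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual lake-health evaluation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakehealth)
```

This vignette is the package's account of its science: the two health
indices it computes, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical conventions chosen where the underlying methodology leaves
room.

## 1. The O/E predictive model

The O/E approach (in the RIVPACS tradition) asks: *of the taxa expected at
this site under minimally disturbed conditions, how many are actually
there?* The expectation is built from reference sites only, and disturbance
at a test site is read from the shortfall of observed against expected
richness.

The model is assembled by `oe_model()` in five steps:

1. **Rare-taxon exclusion** (`filter_rare_taxa`). Taxa occurring at a
   fraction `rare_taxon_max_freq` (default 0.05) **or less** of the
   reference sites are dropped. Rare taxa carry little signal for
   classifying sites and destabilize both the clustering and the
   group-frequency estimates. The boundary is inclusive: a taxon at exactly
   5% occurrence is excluded.
2. **Sørensen dissimilarity** (`sorensen_dissimilarity`) on presence/absence
   vectors, `D = 1 - 2a/(2a + b + c)`. Degenerate sites need a convention:
   the formula is 0/0 for two empty sites, so the package defines two empty
   sites as identical (D = 0, with a warning) and an empty site as maximally
   dissimilar (D = 1) from any non-empty one.
3. **Flexible-β clustering** (`flexible_beta_cluster`). Agglomeration under
   the Lance–Williams recurrence with `α_i = α_j = (1-β)/2`, `γ = 0`;
   β = −0.5 is the space-conserving choice standard for community data. The
   group count is either fixed in the configuration or selected by mean
   silhouette width over candidates 2..min(8, n_ref − 1)
   (`select_n_groups`); silhouette ties break toward the smaller count, the
   more parsimonious model.
4. **Group frequencies** (`group_frequencies`): `f(t|g)` is the fraction of
   group-*g* sites where taxon *t* occurs — the group-conditional occurrence
   probability.
5. **Group classifier** (`fit_group_classifier`): a random forest (default
   100 trees, unlimited depth) from the six natural predictors to the group
   labels, with stratified cross-validated accuracy reported. Only *natural*
   (geomorphological, climatic) predictors may be used: the model must
   predict the *expected* community from features that human disturbance
   does not change, otherwise disturbance would be absorbed into the
   expectation instead of showing up in the score.

Scoring a site (`assess_sites`) multiplies the forest's membership
probabilities into the group frequencies to get per-taxon capture
probabilities `pc(t) = Σ_g p_g f(t|g)`, then applies the threshold:

* `E` = sum of pc over passing taxa (a sum of probabilities, so E is
  generally non-integer);
* `O` = count of *observed* taxa among the passing set.

With threshold `τ > 0` a taxon passes when `pc ≥ τ`; at `τ = 0` the
comparison is strict (`pc > 0`), since a taxon with zero capture probability
carries no information about completeness. E at threshold 0.5 therefore
never exceeds E at threshold 0. O is a count and E a sum: this is the
convention under which O/E has expectation near 1 at reference sites and
lives essentially in [0, 1]. O/E is reported unclamped — sampling noise puts
individual reference sites slightly above 1 — and graded on the five-level
scale (≥ 0.79 Excellent; 0.59–0.79 Healthy; 0.39–0.59 Sub-healthy;
0.19–0.39 General; ≤ 0.19 Poor). Bands are lower-inclusive except that 0.19
itself grades Poor, honouring the "≤ 0.19" convention for the bottom band.

`performance_test()` checks the property that justifies the whole exercise:
the index must separate held-out reference sites from severely damaged
ones. It reports per-set means and SDs of O/E and a separation flag.

**Key assumptions.** Reference sites adequately span the natural gradient;
the community is in quasi-equilibrium with the natural predictors; taxa
occur independently given the group (the pc machinery ignores co-occurrence
structure); detection is complete enough that absence is informative.

## 2. The chemical–biological composite index

Five chemistry indicators (TN, TP, NH₃-N, COD_Mn in the decreasing-is-better
direction; DO increasing) and three biological metrics (richness T, Shannon
diversity H, Simpson dominance D) are standardized linearly to [0, 1] and
aggregated with equal weights:

* chemistry against the class I–V envelope (Cmin, Cmax) of the
  surface-water quality standard, shipped as *editable configuration*
  (`default_standard_bounds()`), with the lake/reservoir column for TP. The
  standard distinguishes lake and river TP limits and the methodology does
  not say which to use; lakes are the subject here, and the bounds are
  user-replaceable either way.
* biology against the 5th/95th percentiles of the metric over **all**
  sampling points, pooled across periods (`bio_percentiles`), with the
  linear-interpolation quantile definition (R type 7). Pooling is what makes
  scores comparable across sites and periods.

Scores falling outside their envelope are **clamped** to [0, 1]; without
clamping, extreme samples would push the composite outside the grade bands
and a single outlier could dominate a site mean.

Aggregation: `i_N = (S_TN + S_TP)/2`, `i_O = (S_DO + S_NH₃N + S_CODMn)/3`,
`i_B = (S_T + S_H + S_D)/3`, and the chemical criterion layer
`i_C = (i_N + i_O)/2`. The composite is `I = a(i_C + i_B)` with `a = 0.5`
over `n = 2` criterion layers.

**A deliberate design decision:** the chemical layer is the *mean* of its
two factor scores. Summing them instead (i_C = i_N + i_O) would give
I = 1.5 for a site with perfect scores, inconsistent with grade bands that
end at 1.0 and with a correction multiplier calibrated so that perfect
scores reach the top of the healthy band. The sum behaviour remains
available (`chemical_sum = TRUE` in `analysis_config()` /
`assess_composite()`) for fidelity experiments, and the choice is logged in
the run report via the config echo.

Grade bands are lower-inclusive: [0.8, 1] healthy, [0.6, 0.8) sub-healthy,
[0.4, 0.6) general, [0.2, 0.4) poor, [0, 0.2) very poor.

Missing indicator values cause the record to be skipped with a message — the
aggregation formulas define no imputation rule, and silently imputing
chemistry would manufacture health grades.

## 3. Community metrics

The methodology names richness T, a "biodiversity index" H and a "dominance
index" D without pinning down formulas. The package uses the dominant
conventions in lake bioassessment: Shannon–Wiener with natural log,
`H = −Σ p_i ln p_i`, and Simpson concentration, `D = Σ p_i²`. Both are
config-switchable in the narrow sense that `shannon_diversity()` takes a
log base; H is maximal (ln T) and D minimal (1/T) exactly at the uniform
community, which the tests verify. Composition summaries
(`composition_breakdown`) report percentages of taxonomic units at phylum
level and within a phylum, or percentages of individuals per site (which
requires abundance data); a `keep` argument collapses minor categories into
a residual `other` so totals remain 100.

## 4. The synthetic study design

Because no field survey ships with the package, `world_spec()` defines a
fully synthetic study whose ground truth every stage can be tested against.
Defaults (the fixture used throughout the test suite):

| parameter | default | rationale |
|---|---|---|
| groups × reference sites | 3 × 5 | small but clusterable reference pool |
| held-out validation sites | 2 per group | reference-quality sites unseen by the fit |
| taxa | 40 (12 characteristic per group + 4 ubiquitous) | regional pool with clear group signatures |
| occurrence probabilities | 0.9 within group / 0.05 outside / 0.7 ubiquitous | strong but noisy group structure |
| predictor noise | CV 0.08 around group centroids | classifiable but not degenerate |
| quarterly degradation levels | 0.02, 0.18, 0.26, 0.10 (Q1..Q4) | see below |
| water-quality noise | 0.08 of each indicator's envelope range | moderate measurement + sampling noise |

Presence is Bernoulli per taxon given the group — the simplest model
consistent with the independence assumption the pc machinery makes.
Impairment (`generate_impaired_sites`) suppresses each *high-occurrence*
taxon (characteristic + ubiquitous) independently with probability equal to
the impairment fraction, so O falls roughly linearly with impairment while
E, driven by the unchanged predictors, stays put: the regime O/E is designed
to detect. Sites at impairment ≥ 0.75 are labelled severely damaged.

The seasonal generator (`generate_waterquality_series`) places each
quarter's chemistry at a planted *degradation level* along the standard
envelope (pollutants at `Cmin + level·range`, DO mirrored) and degrades the
biological metrics with the same level; an optional per-site severity adds
to the level, which is what couples the composite index to the biological
impairment in `run_pipeline()`. The default levels keep an undisturbed
site's chemistry in the healthiest fifth of the envelope — a genuine
reference site should grade healthy on both schemes — with a seasonal
amplitude of about a quarter of the envelope, ordered Q1 < Q4 < Q2 < Q3 so
implied health is Q1 > Q4 > Q2 > Q3 (spring best, autumn worst).

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about field data: spatial autocorrelation among sites,
taxon co-occurrence beyond group membership, detection error and variable
sampling effort, abundance dynamics (counts are i.i.d. Poisson given
presence), inter-annual trends, and any real climatology. Recovery results
on this design show the pipeline's internal consistency, not field validity.

## 5. Numerical conventions and degenerate inputs

* Quantiles: linear interpolation (R type 7) for Q5/Q95.
* Silhouette ties in group-count selection: smaller count wins.
* `E = 0` (no taxon passes the threshold): O/E is undefined; `oe_score()`
  errors and `assess_sites()` records `NA` with a warning naming the site.
* Single-site sets in `performance_test()`: SD reported as 0 with a warning.
* Degenerate envelopes (`Cmax = Cmin`, `Q95 = Q5`): configuration errors
  naming the indicator; no silent division by zero.
* Cross-validation folds exceeding the smallest group: reduced with a
  warning, never below 2.
* All randomness (forest, fold assignment, every generator draw) descends
  from explicit seeds; identical seeds reproduce byte-identical tables.

## 6. Problem sizes used by the test suite

The suite exercises the fixture world (3 × 5 reference sites, 40 taxa) with
20 seeds for the recovery and impairment-monotonicity checks, 50 seeds of a
25-year × 11-site series for the seasonal-ordering check, 100 seeds for
clustering recovery, and 200 random instances of ≤ 8 sites for the
brute-force Lance–Williams oracle comparison — sizes chosen so the whole
suite runs in seconds while the binomial error of each recovery rate stays
well inside the asserted margins.

## 7. Known limitations

* The O/E expectation inherits every bias of the reference-site pool; with
  only simulated references the package cannot advise on reference-site
  screening beyond the role labels it accepts.
* Membership-probability shrinkage (forest votes < 1) biases pc, and hence
  E, slightly toward the overall mean; at the fixture's separability this
  is ~2% of E, visible in held-out O/E means marginally above 1.
* The composite index is only as meaningful as its standard envelope;
  grades move if bounds are edited, which is why the bounds are config and
  echoed in every run report.
* No null-model standardization of O/E variance and no alternative
  dissimilarities are provided; both are out of scope by design.
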
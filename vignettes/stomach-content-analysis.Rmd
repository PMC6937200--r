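---
title: "Stomach-content analysis of pelagic fish surveys with dietstat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stomach-content analysis of pelagic fish surveys with dietstat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietstat)
```

## The problem

Summer trawl surveys of pelagic planktivores (the motivating case is
Northeast Atlantic mackerel feeding in Icelandic waters) collect, per
trawl station, around ten stomachs together with hydrography averaged
over the top 50 m, zooplankton dry-weight biomass from vertical net
hauls, and the haul's catch. Each stomach is read under a microscope:
prey are identified, grouped into about ten taxon groups, counted and
wet-weighed; parasites and unidentifiable matter are recorded but
excluded from all diet statistics. Three questions follow:

1. **What is the diet?** Composition indices and the prey-specific index
   of relative importance (PSIRI), plus an Amundsen-style
   feeding-strategy diagram.
2. **Does the diet differ among areas, years and predator sizes?**
   Distance-based multivariate tests (PERMANOVA on Bray–Curtis
   dissimilarities of fourth-root weights), hierarchical clustering of
   area-pooled diets, and rank tests for univariate contrasts.
3. **What drives feeding success?** Additive models of log stomach
   weight on environmental and biological covariates, ranked by AIC.

The raw stomach records of such surveys are generally not public, so the
package carries a synthetic survey generator with a truth manifest; every
stage of the analysis is exercised and calibrated against data whose
generating process is known exactly.

## Data model and grouping rules

A `stomach_record` holds one fish (length, body weight, the stomach
weight *including* its content, and the prey items); a `station_record`
holds one trawl station. CSV readers/writers round-trip all numeric
fields to full precision, and a column-name dialect map adapts foreign
files.

Grouping conventions, fixed here once:

- **Length groups** S ≤ 33 cm, M 34–38 cm, L ≥ 39 cm. The survey
  literature prints these with inverted inequality signs
  ("≥33cm (S) … ≤39 cm (L)"); the implementation uses the only
  internally consistent reading, under which sub-centimetre lengths
  partition at the same cut points (S up to 33.0, M to 38.0, L above).
- **Time periods** P1–P4 are 6-hour half-open blocks of the local hour,
  [00, 06), [06, 12), [12, 18), [18, 24). Printed period labels of the
  form "00:00–05:00" leave one hour per block unassigned; half-open
  blocks close that gap.
- **Distance-to-shore classes** D1–D4 cut bottom depth at 200, 500 and
  1000 m. (An alternative binning at 100/200/500 m circulates in the
  same literature; the 200/500/1000 m form matches the reported model
  coefficients and is used here.)
- **Sub-areas** N, E, SE, SW, W are polygons supplied by configuration —
  surveys define them on maps, not as coordinates. The default is a
  documented set of five rectangles around Iceland; points on shared
  edges resolve by the fixed precedence N > E > SE > SW > W.
- **Modelling filters**, in this order: drop fish under 25 cm, then drop
  stations left with fewer than 10 stomachs ("more than 9"). The filter
  is idempotent and reports counts removed at each step; model fitting
  refuses tables that have not passed it.
- **Subsampling** of dense zooplankton stomachs scales counts and
  weights by the volume ratio (volumetric proportionality — the natural
  reading of a 1–2 mL aliquot from a mixed sample). Scaled counts are
  kept real-valued rather than rounded, preserving `%N` additivity.

## Diet indices and the PSIRI convention

With `Es` empty of `Ts` stomachs, vacuity is `Vi = 100·Es/Ts`. `%N` and
`%W` are pooled shares of count and weight; `FOi` is the share of
stomachs containing group *i* (empty stomachs stay in the denominator by
default — vacuity is reported separately, and `FOi·(PWi+PNi)/200` then
sums to `100 − Vi`, which is exactly 100 on complete data).

**Prey-specific abundance** has two defensible definitions, and the
difference matters:

- *mean of per-stomach percentages* (the default): over stomachs
  containing *i*, average `100·w_i/total`. This is the form under which
  PSIRI is defined and under which `ΣPSIRI = 100` holds identically on
  complete data over exhaustive, mutually exclusive groups.
- *ratio of pooled sums* (`method = "pooled"`): `100·Σw_i/Σtotals`,
  often transcribed as `ΣWi/ΣSWi`. It weights stomachs by content mass
  and does **not** preserve the PSIRI sum (two stomachs (1, 0) and
  (1, 3) already give `ΣPSIRI = 77.5`).

Published methods sections frequently print the pooled formula while the
index's defining property requires the mean-of-ratios form; dietstat
implements both, defaults to the property-preserving one, and asserts
`ΣPSIRI = 100` only on complete synthetic data (observed tables with
excluded matter sum lower, consistently with the vacuity complement).

The Amundsen diagram plots `(FOi, Pi)` with `Pi` the weight-based
prey-specific abundance (identical to `PWi` under the same convention —
computed through both routes and asserted equal). Quadrants split at the
50/50 midlines, half-open so that a point exactly on a midline falls in
the upper/right quadrant: high FO + high Pi = dominant prey of a
specialised population; low FO + high Pi = individual specialisation
(between-phenotype niche component); high FO + low Pi = generalised
feeding (within-phenotype component); low FO + low Pi = rare prey.

## Distance-based comparisons

Gravimetric diet matrices are fourth-root transformed (the standard
severe down-weighting of dominant prey in community ecology) and turned
into Bray–Curtis dissimilarities `Σ|x−y|/Σ(x+y)`. A pair of all-zero
rows is defined as distance 0 with a warning; the pipeline drops empty
stomachs before multivariate testing instead, since an empty stomach has
no composition to compare.

**PERMANOVA** partitions the sum of squared dissimilarities:
`SS_total = (1/N)Σ_{i<j} d²`, `SS_within = Σ_g (1/n_g)Σ_{i<j∈g} d²`,
pseudo-F = `(SS_between/(a−1))/(SS_within/(N−a))`. With Euclidean
distance on univariate data this reproduces the classical ANOVA F
exactly (a test-suite invariant at 1e-8). Significance comes from free
permutation of sample labels with the +1-corrected p-value; when the
number of distinct relabellings is at most `n_perm`, the exact
permutation distribution is enumerated instead. The two-way additive
design (no interaction, matching the Area/Year/Residual layout of the
motivating study) uses the Gower-centred inner-product matrix with
sequential (type-I) projections — term order matters in unbalanced
designs and is reported; the permutation scheme defaults to unrestricted
shuffling of raw observations, with a within-blocks option. Defaults:
9999 permutations, unadjusted pairwise tables (Bonferroni available) —
matching how such tables are usually printed, with adjustment left to
the reader's design.

**UPGMA** clustering is implemented literally: the distance between
clusters is the size-weighted mean of member distances, ties break by
the lexicographically smallest label pair (making output invariant to
row order), merge heights are provably non-decreasing, and the
dendrogram exports to Newick with ultrametric node ages at half the
merge height, so leaf-to-leaf path lengths equal cophenetic distances.
Reported "percent similarity" is `100·(1 − height)`.

**Kruskal–Wallis / Dunn** implement the standard tie corrections; for
two groups Dunn's z² equals H (checked numerically), and H is invariant
under monotone transforms.

## The additive stomach-weight model

The response is fixed to `log(stomach weight)`; candidate terms are
smooths of zooplankton biomass, bottom depth, salinity, temperature,
log catch, Fulton's condition factor `K = 100·W/L³`, a joint isotropic
surface in (longitude, latitude), and factors for time period,
distance-to-shore class, week and year (reference levels: P1, the
shallowest class — matching the usual reporting). The family is
Gaussian with identity link; smoothness is selected by REML.

The spline/REML engine is the one deliberately delegated numerical
component — mgcv, behind the single entry point `fit_additive_model()`;
basis dimension defaults to k = 10 per 1-D term (3k for the 2-D
surface), configurable, and the pipeline shrinks k below the number of
stations because station-level covariates have one unique value per
station. Everything around the engine is implemented in-package: design
construction from named term subsets, a pairwise-correlation
collinearity screen (exact aliases are errors), exhaustive subset
enumeration with a candidate cap, `ΔAIC`, Akaike weights
`w_i = exp(−Δi/2)/Σexp(−Δj/2)`, and the 95% confidence set (smallest
weight-ordered prefix reaching 0.95 of the total weight — weights are
normalised in the prefix rule, so partial weight vectors behave).
"Deviance explained" is `1 − D_resid/D_null`; adjusted R² is the
engine's definition; both appear in the ranking table.

## The synthetic world

The generator's defaults are the stated world, chosen once:

| quantity | default | rationale |
|---|---|---|
| stomachs per station | 10 | survey protocol |
| empty-stomach probability | 0.083 | the surveyed average vacuity of 8.3% |
| Dirichlet concentration | 50 | stomach-to-stomach compositional scatter large enough to be visible, small enough that area signatures survive pooling |
| content weight | lognormal(log 3, 0.8) g | a few grams of content with right skew, as stomach fullness data show |
| base compositions | copepod-dominated; euphausiids elevated E/SE, large crustaceans N | qualitative mimic of the surveyed spatial pattern; illustrative, not fitted |
| counts | group weight ÷ mean individual mass (copepods 0.3 mg … fish 5 g) | makes `%N ≫ %W` for tiny prey and `%W ≫ %N` for fish, the pattern real tables show |
| covariate truth | `0.7 + 0.25·sin(SST/2) − 0.065·1(P4) + b·log(zoopl) + N(0, 0.3)` | a smooth non-monotone temperature effect, an evening feeding dip of the size reported for such surveys, optional zooplankton effect (b = 0.15 in recovery tests), residual scatter of ~30% on the weight scale |
| fish length | N(36, 3.5) cm clipped to (20, 50) | adult summer size distribution; a small fraction falls under the 25 cm filter |

One master seed drives everything through per-station sub-streams keyed
by station id, so datasets are bit-reproducible and stable under station
re-ordering. `make_null_dataset()` equalises the named factor (area
composition and temperature, year effects, or a covariate effect),
giving exact nulls for calibration; `recovery_report()` scores estimated
vacuity, per-area `%W` and the covariate coefficients (re-estimated by
OLS on the true basis functions, which recovers the truth to machine
precision in the noiseless limit) against the manifest.

What the generator does *not* emulate — and hence what a green test does
not establish: prey-presence sparsity (every non-empty stomach contains
every group at Dirichlet-positive weight, so FO is nearly constant
across groups, unlike real tables where FO spans 1–80%); digestion-state
measurement error; spatial autocorrelation beyond area labels;
evacuation dynamics linking stomach weight to time since feeding. Tests
of FO-dependent behaviour therefore use hand-constructed matrices, not
the generator.

## Numerical choices and edge cases

- Empty stomachs: kept as all-zero diet-matrix rows (vacuity needs
  them), excluded from dissimilarity-based tests, error for composition
  when *all* stomachs are empty.
- Never-observed prey groups: reported absent (`NA`), not as zero rows.
- Degenerate PERMANOVA (zero total SS): flagged, statistics `NA` rather
  than fabricated.
- A constant second factor in the two-way design collapses to the
  one-way result (df 0, `NA` F for the constant term).
- Permutation p-values use the +1 correction, so `p ≥ 1/(n_perm+1)`;
  fixed seeds give bit-identical results and the caller's RNG state is
  restored.
- Report rounding is 1 decimal in percent (the usual printed precision);
  all internal computation is full precision.
- UPGMA tie-breaks and the boundary conventions (length groups, time
  periods, area precedence, Amundsen midlines) are all half-open and
  documented above, so every input maps to exactly one label.

## Known limitations

- The two-way PERMANOVA offers sequential SS only (adequate for the
  additive two-factor layout it implements; no interaction term, no
  type-II/III marginal tests) and no dispersion-homogeneity companion
  test — significant results can reflect dispersion as well as location
  differences.
- The exhaustive candidate search treats the smooth-term pool as the
  search space with factors fixed; it does not search factor subsets.
- Area assignment is plain point-in-polygon on user polygons; no
  geodesic handling near the antimeridian (irrelevant for the default
  region).
- With AIC as the criterion, a spurious ~1-edf smooth term lowers AIC
  with probability ≈ 0.16; exact recovery of a true term subset in any
  single replicate is accordingly capped near 84% per spurious
  candidate, which the calibration tests reflect.

## A complete run

```{r pipeline, eval = FALSE}
out <- run_pipeline(list(
  seed = 42, out_dir = tempfile("dietstat_run_"), n_perm = 999,
  simulate = list(n_stations = 4, years = 2011:2014),
  gam_pool = c("sst", "zooplankton", "depth")))
render_reports(out)
```

The output directory then holds the diet index table, strategy
coordinates, Newick dendrogram with similarity percentages, two-way and
pairwise PERMANOVA tables, the model ranking with confidence-set flags,
a filter report, a stage-by-stage log, and a manifest recording seed,
versions and input hashes — everything needed to regenerate the report
from the directory alone.
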
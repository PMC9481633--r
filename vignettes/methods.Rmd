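---
title: "Methods: from use surveys and toxicity endpoints to bee toxic load maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from use surveys and toxicity endpoints to bee toxic load maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeload)
```

## The model

`beeload` turns three heterogeneous public data streams into two
pollinator-relevant indicators per state × crop group × year, and then
into maps.

**Application rate.** For every compound $c$, state $s$, crop group $g$
and year $t$ with a positive area estimate,

$$ r_{c,s,g,t} = \frac{\text{kg}_{c,s,g,t}}{\text{ha}_{s,g,t}} $$

Rows with positive kg but zero or missing area have an undefined rate;
they are excluded from output but reported, never silently dropped, and
never coerced to zero — a missing use record means "no data", which the
use surveys cannot distinguish from true non-use.

**Bee toxic load.** Aggregating over insecticides only,

$$ L_{s,g,t} = \sum_{c \in \text{insecticides}}
   \frac{r_{c,s,g,t} \times 10^9}{\mathrm{LD50}_c} $$

in honey-bee lethal doses per hectare, computed separately with the
contact and the oral consensus LD50 (µg/bee). The $10^9$ factor is the
kg→µg unit bridge and is dimensionally forced: a rate in kg/ha divided
by a per-bee dose in µg must pass through micrograms to count doses.
Only insecticides enter the aggregate (point estimates dominate their
LD50 evidence, and they dominate aggregate toxicity), but the consensus
table covers fungicides and herbicides too, so users can extend the sum.

**Why lethal doses?** Active ingredients span several orders of
magnitude in bee toxicity, so kilograms are a poor hazard unit; dividing
by the LD50 expresses each compound's application in a common
toxicological currency before summing. The estimate deliberately stops
at loading: no environmental fate, persistence, exposure route
weighting, or synergy between compounds is modeled. The load is linear
(additive across compounds, equivariant under rescaling of kg, monotone
in toxicity), which the test suite checks as properties.

## Consensus LD50 resolution

Toxicity endpoints arrive as a mix of point estimates and censored
bounds, from regulatory and non-regulatory sources, for several routes,
durations and life stages. Processing is:

1. **Standardize**: durations in hours become days (48 h → 2 d).
2. **Filter**: keep acute (≤ 4 days), adult, contact-or-oral records.
3. **Resolve** per compound × route:
   * any point estimates → geometric mean of the preferred point tier
     (regulatory points if any exist, otherwise all points). The
     geometric mean is computed as $\exp(\text{mean}(\log x))$,
     underflow-safe across the ~7 orders of magnitude the values span.
   * otherwise bounds: "less than" values resolve to their minimum;
     failing that, "greater than" values to their maximum. Point-ness
     dominates absolutely — a bound never displaces or shifts a point
     consensus, and regulatory status only selects *among* points.
     When both bound directions coexist without points, the "less
     than" minimum wins (the conservative, more-toxic reading; the
     output flags these rows via `mixed_bounds`).
4. **Impute** the rest: the median of resolved values in the compound's
   mode-of-action group; if the group is empty, the median over all
   resolved insecticides (if no insecticide is resolved at all — a
   degenerate case — the median of everything resolved). Medians use
   the midpoint-of-middle-two convention. Zero resolved compounds
   overall is a hard error: there is nothing to impute from.

The `basis` column records which branch produced every value
(`point_consensus`, `bound_min`, `bound_max`, `moa_median`,
`global_median`), so downstream users can weight or filter by evidence
quality. The resolution is order-invariant and is tested against an
independently written brute-force implementation of the same rules.

A body-weight constant for honey-bee workers (`HONEY_BEE_WORKER_MG`,
120 mg) is exported for users who want to rescale doses to other bee
species; the pipeline itself never applies it.

## Crop-area harmonization

The agricultural census is comprehensive but runs only in 1997, 2002,
2007, 2012 and 2017; the annual survey covers fewer crops. The panel is
built per state × crop: census values win row-level in census years
(no reconciliation is attempted when the two disagree — the census is
simply taken as authoritative), survey values fill other years, and
remaining interior gaps are linearly interpolated between the nearest
surrounding observations. Nothing is extrapolated outside the observed
span: a one-sided fill has no bracketing information. Zero observations
are valid anchors (a crop can disappear from a state). Acres convert to
hectares with the international acre, 0.40468564224 ha, applied exactly
once (a unit tag guards against double conversion). California is
processed against its own key variant (its use data derive from a
different source covering more crops) and recombined. Group areas carry
an `interpolated_fraction` so users can see how much of each cell's
hectares rests on interpolation.

The aggregate load panel is interpolated the same way, per measure
independently (kg/ha, contact doses/ha, oral doses/ha), with filled
rows flagged. Aggregate outputs stop at 2014 by default because
seed-applied pesticides are excluded from the source data afterwards
and contribute substantially to toxic load; `max_year = Inf` overrides.

## Reclassification and mapping

A reclassification table maps each land-cover class code to a predicted
value for one state-year. Conventions:

* noncrop classes (forest, water, developed): `noncrop = 1`, no value;
* crops absent from the underlying use survey: `unsurveyed = 1`;
* double crops (two crops in sequence in one year): use is assumed
  **additive** across the pair. For *aggregate* tables a value is
  present only when both components have estimates; for
  *compound-specific* tables the sum of available components is used
  when at least one is present, since a compound may be used on one
  crop only. `unsurveyed = 0.5` marks pairs with exactly one surveyed
  member. The key stores the surveyed components first, which is how a
  half-surveyed pair's value lookup knows which component to use.

Raster reclassification is a pure per-cell lookup producing a float
value grid plus a coverage grid (`surveyed` / `unsurveyed` / `noncrop` /
`missing_value`). Non-surveyed cells become nodata in the value grid
rather than zero: conflating "no estimate" with "no use" would corrupt
every landscape statistic computed downstream. The default landscape
mean therefore averages surveyed cells only; an explicit opt-in mode
counts all cells with non-surveyed as zero, for users who prefer a
lower-bound reading. Coverage percentages are computed by cell counts,
assuming uniform cell area within a raster — appropriate for projected
land-cover grids at 30 m. Because no GDAL-backed raster library is a
dependency, grids are carried in a small in-package container and
exchanged as ESRI ASCII grid (`.asc`), a plain-text format every GIS
reads; origin, cell size and nodata survive round trips exactly.

## Validation machinery

Paired pipeline/reference estimates are compared with the relative
percent difference $100(a-b)/\tfrac{a+b}{2}$, bounded in $[-200, 200]$
and undefined when both are zero (such pairs are excluded and counted).
Per pesticide category the summary reports n, median and quartiles of
the relative difference, a two-sided one-sample Wilcoxon signed-rank
test of median zero (exact for $n \le 25$ without ties, normal
approximation with continuity correction otherwise; zeros dropped),
Spearman (average-rank ties) and Pearson correlations. Reference rates
can be reconstructed two ways: Method 1 divides the reference total kg
by the pipeline's area estimate; Method 2 multiplies the
rate-on-treated-acres by the treated fraction, converting acre→hectare
exactly once. Known outlier pairs can be excluded up front, and the
count of exclusions is carried in the output. A trend summary bins
|relative difference| by percent of area treated, with a Spearman trend
statistic, to show whether agreement improves for widely used
compounds.

## The synthetic-data generator

`generate_fixture_bundle()` writes every input the pipeline reads, with
exact ground truth, so all downstream modules are testable without
downloads. Design choices:

* **kg draws are lognormal** (default meanlog $\log 5000$, sdlog 1):
  use quantities are heavy-tailed in reality. Low estimates are the
  high estimate times a uniform factor in $[0.6, 1]$; missingness hits
  low and high together, row-wise.
* **crop-area series are affine in year** (a base level plus a small
  trend). This makes exact recovery well-defined: linear interpolation
  over interior gaps reproduces an affine series exactly, so the
  generator can state true hectares — and hence true rates — even when
  `missing_rate_area > 0`. Census rows carry the truth in census
  years; survey rows in census years are deliberately distorted
  (±10%) to verify census precedence.
* **endpoint sets are planted per compound × route** to resolve to a
  known target through a known basis (regulatory-point pairs whose
  geometric mean is the target, bound-only sets, etc.), with decoys
  (larval, 10-day, wrong-route, hour-denominated) always present so
  the acute-adult filter is exercised on every run. Two insecticides
  are left unresolved by default: one lands in a populated
  mode-of-action group (median imputation path), one in a singleton
  group (global median path). Their ground truth is the generator's
  own median over the values it planted — trivial arithmetic, not a
  call into the pipeline.
* **rasters are multinomial cells** from a configurable class mix
  (default: ten surveyed crop classes, two double-crop classes, an
  unsurveyed crop, three noncrop classes), with 30 m cells; the exact
  class census is recorded as truth. No spatial autocorrelation is
  simulated — reclassification is per-cell, so none is needed to test
  it.
* the generator is fully deterministic under its seed: fixtures are
  byte-identical across runs.

**What passing these tests does and does not show.** Exact recovery on
fixtures verifies the *mechanics* — joins, unit bridges, precedence
rules, interpolation, aggregation — not the realism of any estimate.
Real use surveys have structured (not uniform) missingness, real
acreage is not affine in time, real endpoint tables carry unit
ambiguity and species mixtures the generator does not emulate, and real
land cover is spatially autocorrelated and misclassified at crop edges.
Conclusions about actual landscapes require the real source datasets;
the fixtures establish that, given those inputs, the arithmetic is
right.

## Numerical and scale choices

Default test problem sizes — 5 states × 10 groups × 6 years × 20
compounds for end-to-end recovery, 200 random endpoint sets for the
consensus oracle, 100 affine series, 50 random 20×20 rasters, 300–1000
validation pairs — are chosen so each check exercises every code path
(all bases, both table kinds, all coverage classes) while the whole
suite runs in seconds; the properties verified are size-independent.
Recovery tolerances are $10^{-9}$ relative against floating-point
ground truth; identities (landscape mean, double-crop additivity,
antisymmetry) hold to $10^{-12}$ or exactly. Ties in Spearman
correlations use average ranks; quantiles use R's default type-7
definition.

## Known limitations

Estimates are state × crop-group × year averages downscaled by land
cover; they are not field-level measurements, and local variation is
not represented. The LD50 basis is acute adult honey-bee toxicity:
chronic effects, larval toxicity and other species are out of scope
(body-weight rescaling is left to the user). County-level inputs,
suppressed-value estimation, reprojection/mosaicking of rasters, and
live database queries are likewise out of scope; the package operates
on already-exported tables.
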
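# beeload

Pesticide application rates, honey-bee toxic load, and landscape
pesticide mapping for pollinator research.

## The problem

Pesticide exposure is a key stressor for wild and managed pollinators,
but public pesticide-use data are scattered across agencies, reported at
state or county scale, and expressed in kilograms — a unit that says
little about hazard when active ingredients differ by orders of
magnitude in bee toxicity. `beeload` implements a reproducible pipeline
that synthesizes three kinds of public data into pollinator-relevant
indicators:

* **pesticide use surveys** — kg of each active ingredient applied per
  state × crop group × year, with "low" and "high" estimate variants
  that differ in the treatment of survey missingness (the pipeline
  defaults to low);
* **crop acreage** — a five-yearly agricultural census merged with
  annual surveys into a complete hectares panel (census wins in census
  years; interior gaps are filled by linear interpolation within each
  state-crop series, never extrapolated);
* **honey-bee acute toxicity** — heterogeneous contact and oral LD50
  endpoints (point estimates, censored ">x"/"<x" bounds, regulatory and
  non-regulatory provenance) resolved into one consensus value per
  compound and route.

From these it computes, for every state × crop group × year:

* **application rate** of each compound: `rate = kg / ha`;
* **bee toxic load**, the aggregate insecticide hazard in honey-bee
  lethal doses per hectare:

  `load = Σ_insecticides rate_i (kg/ha) × 1e9 (µg/kg) / LD50_i (µg/bee)`

  computed on both a contact- and an oral-toxicity basis, and truncated
  at 2014 by default because seed-applied pesticides (a dominant
  contributor) are excluded from the source data after that year.

The consensus LD50 uses a fixed preference hierarchy: point estimates
always beat censored bounds; among points, regulatory estimates are
preferred and pooled by geometric mean; "less than" bounds resolve to
their minimum and "greater than" bounds to their maximum. Compounds with
no usable endpoints receive the median of their mode-of-action group,
falling back to the median over all resolved insecticides.

Finally, the package links these panels to categorical land-cover
rasters: it builds reclassification tables (land-cover class → predicted
kg/ha or doses/ha, with additive double-crop accounting and explicit
`unsurveyed`/`noncrop` flags), reclassifies rasters into predicted
loading maps with a companion coverage grid, computes landscape means,
and summarizes survey coverage. A validation module implements the
cross-checks used to compare synthesized estimates against an
independent survey (relative percent difference, signed-rank tests,
Spearman/Pearson correlations, and the two reference-rate
reconstructions "Method 1" `kg / ha` and "Method 2"
`rate-on-treated-acres × fraction treated`).

Everything is testable offline: a deterministic synthetic-data generator
(`sim_config()` / `generate_fixture_bundle()`) emulates all the source
datasets with known ground truth.

## Worked example

```r
library(beeload)

cfg    <- sim_config(seed = 5, n_states = 3, years = 1997:2004)
bundle <- generate_fixture_bundle(cfg, "demo")
res    <- run_pipeline("demo", variant = "low")

# most orally toxic insecticides in the consensus LD50 table
head(dplyr::arrange(subset(res$ld50, route == "oral" &
                             category == "insecticide"),
                    ld50_ug_per_bee)[c("compound", "ld50_ug_per_bee",
                                       "basis")], 4)
#>   compound       ld50_ug_per_bee basis
#> 1 INSECTICIDE_05          0.0256 point_consensus
#> 2 INSECTICIDE_08          0.0558 bound_min
#> 3 INSECTICIDE_02          0.113  bound_max
#> 4 INSECTICIDE_06          0.652  point_consensus

# aggregate bee toxic load for corn in one state
head(subset(res$loads, state == "AL" & usgs_crop_group == "corn"), 3)
#>   state usgs_crop_group  year insecticide_kg_per_ha lethal_doses_per_ha_contact
#> 1 AL    corn             1997                 0.197                 1255510287
#> 2 AL    corn             1998                 0.159                 1296017667
#> 3 AL    corn             1999                 0.453                 7288613876
```

The LD50 column is micrograms per bee (smaller = more toxic; `basis`
records how the value was resolved). `lethal_doses_per_ha_contact` says
that, e.g., the insecticides applied to corn in this synthetic state in
1997 carried about 1.3 billion honey-bee contact LD50 doses per hectare.

Mapping the 2002 oral-basis loads onto the bundled land-cover raster:

```r
vals <- with(subset(res$loads, year == 2002 & state == "AL"),
             setNames(lethal_doses_per_ha_oral, usgs_crop_group))
tab <- build_reclass_table(vals, res$keys$landcover, "aggregate",
                           state = "AL", year = 2002)
lr  <- reclass_raster(read_asc("demo/landcover.asc"), tab)
landscape_mean(lr)
#> [1] 2538675222
unlist(coverage_summary(read_asc("demo/landcover.asc"), res$keys$landcover))
#>         pct_total_surveyed      pct_cropland_surveyed pct_cropland_crop_specific
#>                   80.22222                   97.37020                   78.46093
```

The landscape mean averages predicted loading over surveyed cells only;
the coverage summary reports what share of the landscape (and of its
cropland) the underlying use survey actually represents.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/beeload` (`beeload simulate`, `build-ld50`, `build-area`,
`build-rates`, `build-toxload`, `make-reclass`, `reclass-raster`,
`coverage`).

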
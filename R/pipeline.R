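#' Run the full synthesis pipeline on a fixture or data directory
#'
#' Convenience orchestrator over the module functions: loads the three
#' crosswalk keys, builds the consensus LD50 table from the two endpoint
#' exports, harmonizes census and survey acreage into the crop-group
#' hectares panel, computes compound application rates for the chosen
#' estimate variant, aggregates insecticide bee toxic load (truncated at
#' `max_year`), and fills interior gaps in the load panel by temporal
#' interpolation.
#'
#' The directory must contain files named as written by
#' [generate_fixture_bundle()]: `crop_key.csv`, `compound_key.csv`,
#' `landcover_key.csv`, `use.csv`, `area_census.csv`, `area_survey.csv`,
#' `tox_ecotox.csv`, `tox_ppdb.csv`.
#'
#' @param dir Input directory.
#' @param variant `"low"` (default) or `"high"` kg estimate.
#' @param max_year Truncation year for the aggregate load panel
#'   (default 2014).
#' @return List with elements `keys` (list of the three key tibbles),
#'   `ld50`, `area`, `rates`, `loads`.
#' @export
run_pipeline <- function(dir, variant = c("low", "high"), max_year = 2014) {
  variant <- match.arg(variant)
  path <- function(f) file.path(dir, f)
  keys <- list(
    crop = load_key(path("crop_key.csv"), "crop"),
    compound = load_key(path("compound_key.csv"), "compound"),
    landcover = load_key(path("landcover_key.csv"), "landcover")
  )
  ld50 <- build_ld50_table(path("tox_ecotox.csv"), path("tox_ppdb.csv"),
                           keys$compound)
  area <- build_area(read_area_csv(path("area_census.csv")),
                     read_area_csv(path("area_survey.csv")),
                     keys$crop)
  rates <- compute_rates(read_use_csv(path("use.csv")), area, variant)
  loads <- compute_toxic_load(rates, ld50, keys$compound,
                              max_year = max_year)
  loads <- interpolate_loads(loads)
  list(keys = keys, ld50 = ld50, area = area, rates = rates, loads = loads)
}
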
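# Small in-code fixture builders shared across test files.

make_endpoint <- function(route = "contact", value = 1, qualifier = "point",
                          regulatory = FALSE, exposure_days = 2,
                          life_stage = "adult", source = "ecotox") {
  tibble::tibble(route = route, value_ug_per_bee = value,
                 qualifier = qualifier, regulatory = regulatory,
                 exposure_days = exposure_days, life_stage = life_stage,
                 source = source)
}

make_endpoints <- function(...) dplyr::bind_rows(...)

mini_compound_key <- function() {
  tibble::tibble(
    usgs_name = c("ALPHA", "BETA", "GAMMA", "DELTA", "OMEGA", "ZETA"),
    casrn = NA_character_,
    category = c("insecticide", "insecticide", "insecticide", "insecticide",
                 "herbicide", "herbicide"),
    moa_group = c("IRAC_1", "IRAC_1", "IRAC_1", "IRAC_9", "HRAC_1", "HRAC_1"),
    usda_name = NA_character_
  )
}

mini_landcover_key <- function() {
  beeload::load_key(
    write_landcover_csv(tibble::tribble(
      ~cdl_code, ~cdl_name, ~kind, ~component_groups, ~surveyed_components,
      ~california_variant,
      1L, "CORN", "single_crop", "corn", 1L, FALSE,
      5L, "SOYBEANS", "single_crop", "soybeans", 1L, FALSE,
      23L, "WHEAT", "single_crop", "wheat", 1L, FALSE,
      26L, "DBL WHEAT/SOY", "double_crop", "wheat;soybeans", 2L, FALSE,
      226L, "DBL OATS/CORN", "double_crop", "corn;other_crops", 1L, FALSE,
      240L, "OATS", "single_crop", "other_crops", 0L, FALSE,
      141L, "FOREST", "noncrop", "", 0L, FALSE
    )), "landcover")
}

write_landcover_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path, progress = FALSE)
  path
}

mini_area <- function(states = "PA", groups = c("corn", "soybeans"),
                      years = 1997:2000, hectares = 100) {
  expand.grid(state = states, usgs_crop_group = groups, year = years,
              stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::mutate(hectares = hectares, interpolated_fraction = 0)
}

mini_use <- function(compounds, states = "PA", groups = "corn",
                     years = 1997, kg = 50) {
  grid <- expand.grid(compound = compounds, state = states,
                      usgs_crop_group = groups, year = years,
                      stringsAsFactors = FALSE)
  tibble::tibble(compound = grid$compound, state = grid$state,
                 usgs_crop_group = grid$usgs_crop_group,
                 year = as.integer(grid$year),
                 kg_low = kg, kg_high = kg)
}

mini_ld50 <- function(compounds, contact, oral) {
  dplyr::bind_rows(
    tibble::tibble(compound = compounds, route = "contact",
                   ld50_ug_per_bee = contact, basis = "point_consensus",
                   n_endpoints_used = 1L),
    tibble::tibble(compound = compounds, route = "oral",
                   ld50_ug_per_bee = oral, basis = "point_consensus",
                   n_endpoints_used = 1L)
  )
}
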
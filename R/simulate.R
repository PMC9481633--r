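# The 48 contiguous states; the panels and fixtures draw from this set.
CONTIGUOUS_STATES <- c(
  "AL", "AZ", "AR", "CA", "CO", "CT", "DE", "FL", "GA", "ID", "IL", "IN",
  "IA", "KS", "KY", "LA", "ME", "MD", "MA", "MI", "MN", "MS", "MO", "MT",
  "NE", "NV", "NH", "NJ", "NM", "NY", "NC", "ND", "OH", "OK", "OR", "PA",
  "RI", "SC", "SD", "TN", "TX", "UT", "VT", "VA", "WA", "WV", "WI", "WY"
)

default_class_mix <- function() {
  c(`1` = 0.18, `5` = 0.15, `23` = 0.08, `36` = 0.05, `37` = 0.12,
    `2` = 0.03, `3` = 0.02, `54` = 0.04, `68` = 0.03, `21` = 0.05,
    `26` = 0.03, `226` = 0.02, `240` = 0.02, `141` = 0.10, `111` = 0.04,
    `121` = 0.04)
}

#' Configuration for the synthetic fixture generator
#'
#' Defines the study conditions the fixtures emulate: a state by
#' crop-group by year pesticide use panel with low/high estimate
#' variants and structured missingness, census-every-five-years plus
#' annual-survey acreage with interior gaps, heterogeneous toxicity
#' endpoints (points, censored bounds, regulatory and non-regulatory
#' provenance, larval/chronic/hour-unit decoys), crosswalk keys, and a
#' small categorical land-cover raster with known class frequencies
#' including double-crop and noncrop classes.
#'
#' @param seed Integer seed; the generator is fully deterministic given
#'   it.
#' @param n_states Number of states (>= 1), taken from the head of the
#'   contiguous-state list (which places California fourth, so
#'   `n_states >= 4` exercises the California key variant).
#' @param groups Crop groups to include (default all ten).
#' @param n_compounds Named integer vector: compounds per category
#'   (default 10 insecticides, 5 fungicides, 5 herbicides).
#' @param years Year range within 1997--2017 (must include at least one
#'   census year).
#' @param missing_rate_use Probability a use row's kg values are
#'   missing (survey non-coverage), in \[0, 1).
#' @param missing_rate_area Probability an interior non-census survey
#'   acreage row is dropped, in \[0, 1).
#' @param use_meanlog,use_sdlog Lognormal location/spread for kg-applied
#'   draws (pesticide use is heavy-tailed).
#' @param ld50_ranges Named list of positive `c(min, max)` LD50 ranges
#'   (micrograms per bee) per category; insecticide toxicity spans
#'   orders of magnitude below herbicides/fungicides.
#' @param raster_size `c(rows, cols)` of the land-cover raster.
#' @param class_mix Named numeric: land-cover code to cell frequency,
#'   summing to 1 (default mix includes two double-crop classes, an
#'   unsurveyed crop and three noncrop classes).
#' @param unresolved_insecticides Number of insecticides (0--2) left
#'   without usable endpoints to exercise the imputation paths (the
#'   first takes the mode-of-action median, the second the global
#'   insecticide median).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_states = 5L,
                       groups = crop_groups(),
                       n_compounds = c(insecticide = 10L, fungicide = 5L,
                                       herbicide = 5L),
                       years = 1997:2008,
                       missing_rate_use = 0.1,
                       missing_rate_area = 0.1,
                       use_meanlog = log(5000),
                       use_sdlog = 1,
                       ld50_ranges = list(insecticide = c(0.01, 50),
                                          fungicide = c(20, 200),
                                          herbicide = c(20, 200)),
                       raster_size = c(60L, 60L),
                       class_mix = default_class_mix(),
                       unresolved_insecticides = 2L) {
  stopifnot(n_states >= 1, n_states <= length(CONTIGUOUS_STATES))
  if (!all(groups %in% crop_groups())) {
    stop("unknown crop group(s): ",
         paste(setdiff(groups, crop_groups()), collapse = ", "),
         call. = FALSE)
  }
  if (any(n_compounds < 0) || sum(n_compounds) == 0) {
    stop("impossible config: need at least one compound", call. = FALSE)
  }
  stopifnot(all(years >= 1997), all(years <= 2017))
  if (!any(years %in% CENSUS_YEARS)) {
    stop("years must include at least one census year", call. = FALSE)
  }
  stopifnot(missing_rate_use >= 0, missing_rate_use < 1,
            missing_rate_area >= 0, missing_rate_area < 1)
  if (abs(sum(class_mix) - 1) > 1e-9) {
    stop("class_mix frequencies must sum to 1", call. = FALSE)
  }
  for (r in ld50_ranges) stopifnot(all(r > 0), r[2] >= r[1])
  if (unresolved_insecticides > 0 &&
      n_compounds[["insecticide"]] < unresolved_insecticides + 2) {
    stop("need at least ", unresolved_insecticides + 2,
         " insecticides to leave ", unresolved_insecticides, " unresolved",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_states = as.integer(n_states),
         groups = groups, n_compounds = n_compounds,
         years = as.integer(years), missing_rate_use = missing_rate_use,
         missing_rate_area = missing_rate_area, use_meanlog = use_meanlog,
         use_sdlog = use_sdlog, ld50_ranges = ld50_ranges,
         raster_size = as.integer(raster_size), class_mix = class_mix,
         unresolved_insecticides = as.integer(unresolved_insecticides)),
    class = "sim_config"
  )
}

make_casrn <- function(i) {
  body <- sprintf("%06d-%02d", 100003L + 97L * i, 10L + (i * 7L) %% 90L)
  digits <- as.integer(strsplit(gsub("-", "", body), "")[[1]])
  check <- sum(rev(digits) * seq_along(digits)) %% 10L
  paste0(body, "-", check)
}

sim_crop_key <- function(groups) {
  base <- tibble::tribble(
    ~usda_crop_name, ~usgs_crop_group, ~area_item, ~california_only,
    "ALFALFA HAY", "alfalfa", "harvested_acres", FALSE,
    "CORN, GRAIN", "corn", "harvested_acres", FALSE,
    "CORN, SILAGE", "corn", "harvested_acres", FALSE,
    "COTTON", "cotton", "harvested_acres", FALSE,
    "APPLES", "orchards_grapes", "bearing_nonbearing_acres", FALSE,
    "GRAPES", "orchards_grapes", "bearing_nonbearing_acres", FALSE,
    "BARLEY", "other_crops", "harvested_acres", FALSE,
    "PEANUTS", "other_crops", "harvested_acres", FALSE,
    "HAY (EXCL ALFALFA)", "pasture_hay", "harvested_acres", FALSE,
    "RICE", "rice", "harvested_acres", FALSE,
    "SOYBEANS", "soybeans", "harvested_acres", FALSE,
    "TOMATOES", "vegetables_fruit", "harvested_acres", FALSE,
    "POTATOES", "vegetables_fruit", "harvested_acres", FALSE,
    "WHEAT, WINTER", "wheat", "harvested_acres", FALSE,
    "WHEAT, SPRING", "wheat", "harvested_acres", FALSE,
    "OLIVES", "orchards_grapes", "bearing_nonbearing_acres", TRUE,
    "SAFFLOWER", "other_crops", "harvested_acres", TRUE
  )
  base[base$usgs_crop_group %in% groups, , drop = FALSE]
}

sim_compound_key <- function(n_compounds) {
  rows <- list()
  idx <- 0L
  for (cat in names(n_compounds)) {
    n <- n_compounds[[cat]]
    if (n == 0) next
    for (i in seq_len(n)) {
      idx <- idx + 1L
      moa_prefix <- switch(cat, insecticide = "IRAC", fungicide = "FRAC",
                           herbicide = "HRAC", "MOA")
      rows[[idx]] <- tibble::tibble(
        usgs_name = sprintf("%s_%02d", toupper(cat), i),
        casrn = make_casrn(idx),
        category = cat,
        moa_group = sprintf("%s_%d", moa_prefix, (i - 1L) %% 4L + 1L),
        usda_name = if (i %% 7L == 0L) NA_character_ else
          sprintf("%s %02d", toupper(cat), i)
      )
    }
  }
  dplyr::bind_rows(rows)
}

sim_landcover_key <- function() {
  tibble::tribble(
    ~cdl_code, ~cdl_name, ~kind, ~component_groups, ~surveyed_components,
    ~california_variant,
    1L, "CORN", "single_crop", "corn", 1L, FALSE,
    2L, "COTTON", "single_crop", "cotton", 1L, FALSE,
    3L, "RICE", "single_crop", "rice", 1L, FALSE,
    5L, "SOYBEANS", "single_crop", "soybeans", 1L, FALSE,
    21L, "BARLEY", "single_crop", "other_crops", 1L, FALSE,
    23L, "SPRING WHEAT", "single_crop", "wheat", 1L, FALSE,
    36L, "ALFALFA", "single_crop", "alfalfa", 1L, FALSE,
    37L, "OTHER HAY", "single_crop", "pasture_hay", 1L, FALSE,
    54L, "TOMATOES", "single_crop", "vegetables_fruit", 1L, FALSE,
    68L, "APPLES", "single_crop", "orchards_grapes", 1L, FALSE,
    26L, "DBL CROP WINWHT/SOYBEANS", "double_crop", "wheat;soybeans", 2L, FALSE,
    226L, "DBL CROP OATS/CORN", "double_crop", "corn;other_crops", 1L, FALSE,
    240L, "OATS", "single_crop", "other_crops", 0L, FALSE,
    141L, "DECIDUOUS FOREST", "noncrop", "", 0L, FALSE,
    111L, "OPEN WATER", "noncrop", "", 0L, FALSE,
    121L, "DEVELOPED", "noncrop", "", 0L, FALSE
  )
}

# Resolution patterns for planted endpoint sets. Each returns endpoints
# whose consensus is exactly the target L, plus the basis they resolve to.
plant_endpoints <- function(L, pattern) {
  point <- function(v, reg, days = 2, unit = "days") {
    tibble::tibble(value_ug_per_bee = v, qualifier = "point",
                   regulatory = reg, exposure_duration = days,
                   duration_unit = unit, life_stage = "adult")
  }
  bound <- function(v, q) {
    tibble::tibble(value_ug_per_bee = v, qualifier = q, regulatory = FALSE,
                   exposure_duration = 2, duration_unit = "days",
                   life_stage = "adult")
  }
  switch(as.character(pattern),
    # regulatory points dominate a non-regulatory decoy; one duration in hours
    `0` = list(eps = dplyr::bind_rows(point(L * 1.5, TRUE),
                                      point(L / 1.5, TRUE, days = 48,
                                            unit = "hours"),
                                      point(L * 3, FALSE)),
               basis = "point_consensus"),
    # single regulatory point; a greater-than bound must be ignored
    `1` = list(eps = dplyr::bind_rows(point(L, TRUE),
                                      bound(L * 10, "greater_than")),
               basis = "point_consensus"),
    # non-regulatory points only
    `2` = list(eps = dplyr::bind_rows(point(L * 2, FALSE),
                                      point(L / 2, FALSE)),
               basis = "point_consensus"),
    # greater-than bounds only: maximum wins
    `3` = list(eps = dplyr::bind_rows(bound(L / 2, "greater_than"),
                                      bound(L, "greater_than")),
               basis = "bound_max"),
    # less-than bounds only: minimum wins
    `4` = list(eps = dplyr::bind_rows(bound(L, "less_than"),
                                      bound(L * 2, "less_than")),
               basis = "bound_min")
  )
}

decoy_endpoints <- function() {
  tibble::tibble(
    value_ug_per_bee = c(0.5, 999, 77),
    qualifier = "point",
    regulatory = FALSE,
    exposure_duration = c(2, 10, 2),
    duration_unit = "days",
    life_stage = c("larva", "adult", "adult"),
    route_override = c(NA, NA, "other")
  )
}

sim_toxicity <- function(config, compound_key) {
  n_unres <- config$unresolved_insecticides
  ins <- compound_key$usgs_name[compound_key$category == "insecticide"]
  unresolved <- if (n_unres > 0) utils::tail(ins, n_unres) else character(0)
  # the last unresolved compound gets a singleton mode-of-action group so
  # it must fall through to the global insecticide median
  if (n_unres >= 2) {
    compound_key$moa_group[compound_key$usgs_name == unresolved[n_unres]] <-
      "IRAC_99"
  }
  eps <- list()
  truth <- list()
  for (i in seq_len(nrow(compound_key))) {
    cmp <- compound_key$usgs_name[i]
    cat <- compound_key$category[i]
    rng <- config$ld50_ranges[[cat]]
    if (is.null(rng)) rng <- c(1, 100)
    for (route in c("contact", "oral")) {
      L <- exp(stats::runif(1, log(rng[1]), log(rng[2])))
      if (cmp %in% unresolved) {
        # only decoys: filtered out, so the compound stays unresolved
        d <- decoy_endpoints()
        d$route <- ifelse(is.na(d$route_override), route, d$route_override)
        d$route_override <- NULL
        d$casrn <- compound_key$casrn[i]
        eps[[length(eps) + 1]] <- d
        next
      }
      planted <- plant_endpoints(L, (i + (route == "oral")) %% 5)
      p <- planted$eps
      p$route <- route
      p$casrn <- compound_key$casrn[i]
      eps[[length(eps) + 1]] <- p
      if (i %% 3 == 1 && route == "contact") {
        # sprinkle filter-exercising decoys over resolved compounds too
        d <- decoy_endpoints()
        d$route <- ifelse(is.na(d$route_override), route, d$route_override)
        d$route_override <- NULL
        d$casrn <- compound_key$casrn[i]
        eps[[length(eps) + 1]] <- d
      }
      truth[[length(truth) + 1]] <- tibble::tibble(
        compound = cmp, category = cat,
        moa_group = compound_key$moa_group[i], route = route,
        ld50_ug_per_bee = L, basis = planted$basis
      )
    }
  }
  truth <- dplyr::bind_rows(truth)
  # ground truth for unresolved compounds: medians of the planted values
  for (cmp in unresolved) {
    moa <- compound_key$moa_group[compound_key$usgs_name == cmp]
    for (route in c("contact", "oral")) {
      pool <- truth$ld50_ug_per_bee[truth$moa_group == moa &
                                      truth$route == route]
      if (length(pool) > 0) {
        value <- stats::median(pool)
        basis <- "moa_median"
      } else {
        gp <- truth$ld50_ug_per_bee[truth$category == "insecticide" &
                                      truth$route == route &
                                      !truth$compound %in% unresolved]
        value <- stats::median(gp)
        basis <- "global_median"
      }
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        compound = cmp, category = "insecticide", moa_group = moa,
        route = route, ld50_ug_per_bee = value, basis = basis))
    }
  }
  eps <- dplyr::bind_rows(eps)
  eps <- eps[c("casrn", "route", "value_ug_per_bee", "qualifier",
               "regulatory", "exposure_duration", "duration_unit",
               "life_stage")]
  # split across the two source exports
  half <- seq_len(nrow(eps)) %% 2 == 0
  list(ecotox = eps[!half, , drop = FALSE], ppdb = eps[half, , drop = FALSE],
       truth = dplyr::arrange(truth, .data$compound, .data$route),
       compound_key = compound_key)
}

sim_area <- function(config, crop_key) {
  states <- utils::head(CONTIGUOUS_STATES, config$n_states)
  years <- config$years
  rows <- list()
  truth <- list()
  for (st in states) {
    key <- if (st == "CA") crop_key else
      crop_key[!crop_key$california_only, , drop = FALSE]
    for (i in seq_len(nrow(key))) {
      base <- stats::rlnorm(1, log(2e5), 0.5)
      slope <- base * stats::runif(1, -0.02, 0.04)
      acres <- base + slope * (years - min(years))
      crop <- key$usda_crop_name[i]
      truth[[length(truth) + 1]] <- tibble::tibble(
        state = st, crop = crop, usgs_crop_group = key$usgs_crop_group[i],
        year = years, acres = acres)
      cen_years <- intersect(years, CENSUS_YEARS)
      rows[[length(rows) + 1]] <- tibble::tibble(
        program = "CENSUS", state = st, commodity = crop, year = cen_years,
        value = acres[match(cen_years, years)])
      # survey reports every year; census-year survey values are distorted
      # (census wins anyway), and interior non-census rows can go missing
      sv <- acres
      distort <- years %in% CENSUS_YEARS
      sv[distort] <- sv[distort] * stats::runif(sum(distort), 0.9, 1.1)
      interior <- years > min(years) & years < max(years) &
        !years %in% CENSUS_YEARS
      drop <- interior & stats::runif(length(years)) < config$missing_rate_area
      rows[[length(rows) + 1]] <- tibble::tibble(
        program = "SURVEY", state = st, commodity = crop, year = years[!drop],
        value = sv[!drop])
    }
  }
  truth <- dplyr::bind_rows(truth)
  group_truth <- dplyr::summarise(
    dplyr::group_by(truth, .data$state, .data$usgs_crop_group, .data$year),
    hectares = sum(.data$acres) * ACRES_TO_HECTARES, .groups = "drop")
  list(records = dplyr::bind_rows(rows), truth_hectares = group_truth)
}

sim_use <- function(config, compound_key, area_truth) {
  states <- utils::head(CONTIGUOUS_STATES, config$n_states)
  grid <- expand.grid(compound = compound_key$usgs_name, state = states,
                      usgs_crop_group = config$groups, year = config$years,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  kg_high <- stats::rlnorm(n, config$use_meanlog, config$use_sdlog)
  kg_low <- kg_high * stats::runif(n, 0.6, 1)
  missing <- stats::runif(n) < config$missing_rate_use
  kg_high[missing] <- NA_real_
  kg_low[missing] <- NA_real_
  use <- tibble::tibble(
    compound = grid$compound, state = grid$state,
    usgs_crop_group = grid$usgs_crop_group, year = as.integer(grid$year),
    kg_low = kg_low, kg_high = kg_high)
  truth_rates <- dplyr::left_join(use, area_truth,
                                  by = c("state", "usgs_crop_group", "year"))
  truth_rates$rate_low <- truth_rates$kg_low / truth_rates$hectares
  truth_rates$rate_high <- truth_rates$kg_high / truth_rates$hectares
  list(use = use,
       truth_rates = truth_rates[c("compound", "state", "usgs_crop_group",
                                   "year", "rate_low", "rate_high")])
}

sim_true_loads <- function(truth_rates, ld50_truth, compound_key,
                           max_year = 2014) {
  ins <- compound_key$usgs_name[compound_key$category == "insecticide"]
  r <- truth_rates[truth_rates$compound %in% ins &
                     truth_rates$year <= max_year &
                     !is.na(truth_rates$rate_low), , drop = FALSE]
  wide <- tidyr::pivot_wider(
    ld50_truth[c("compound", "route", "ld50_ug_per_bee")],
    names_from = "route", values_from = "ld50_ug_per_bee")
  r <- dplyr::left_join(r, wide, by = "compound")
  dplyr::summarise(
    dplyr::group_by(r, .data$state, .data$usgs_crop_group, .data$year),
    insecticide_kg_per_ha = sum(.data$rate_low),
    lethal_doses_per_ha_contact = sum(.data$rate_low * 1e9 / .data$contact),
    lethal_doses_per_ha_oral = sum(.data$rate_low * 1e9 / .data$oral),
    .groups = "drop")
}

#' Generate a complete synthetic fixture bundle with ground truth
#'
#' Writes every input the pipeline consumes -- the three crosswalk keys,
#' a low/high pesticide use panel, census and survey acreage files, two
#' toxicity endpoint exports (with larval, chronic, hour-unit and
#' wrong-route decoys that the acute-adult filter must remove), and a
#' categorical land-cover raster -- and returns the exact ground truth
#' (true rates, true toxic loads, true consensus LD50s, true crop-group
#' hectares, true raster class counts) against which pipeline output can
#' be checked.
#'
#' Crop-area series are affine in year, so interior survey gaps are
#' recovered exactly by linear interpolation and ground-truth rates stay
#' exact under area missingness. Endpoint sets are planted so that each
#' resolved compound's consensus equals a known target value through a
#' known basis; unresolved compounds' truth is the median of the planted
#' values their imputation tier pools over.
#'
#' The bundle is byte-identical across runs with the same configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (list of ground-truth tibbles) and `config`.
#' @export
generate_fixture_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  crop_key <- sim_crop_key(config$groups)
  compound_key <- sim_compound_key(config$n_compounds)
  landcover_key <- sim_landcover_key()
  tox <- sim_toxicity(config, compound_key)
  compound_key <- tox$compound_key # moa groups may be adjusted
  area <- sim_area(config, crop_key)
  use <- sim_use(config, compound_key, area$truth_hectares)
  true_loads <- sim_true_loads(use$truth_rates, tox$truth, compound_key)
  n_cells <- prod(config$raster_size)
  codes <- sample(as.integer(names(config$class_mix)), n_cells,
                  replace = TRUE, prob = config$class_mix)
  counts <- table(factor(codes, levels = sort(as.integer(names(config$class_mix)))))
  raster <- raster_grid(matrix(codes, nrow = config$raster_size[1]),
                        cellsize = 30)
  paths <- c(
    crop_key = file.path(dir, "crop_key.csv"),
    compound_key = file.path(dir, "compound_key.csv"),
    landcover_key = file.path(dir, "landcover_key.csv"),
    use = file.path(dir, "use.csv"),
    area_census = file.path(dir, "area_census.csv"),
    area_survey = file.path(dir, "area_survey.csv"),
    ecotox = file.path(dir, "tox_ecotox.csv"),
    ppdb = file.path(dir, "tox_ppdb.csv"),
    landcover = file.path(dir, "landcover.asc"),
    truth_rates = file.path(dir, "truth_rates.csv"),
    truth_loads = file.path(dir, "truth_loads.csv"),
    truth_ld50 = file.path(dir, "truth_ld50.csv"),
    truth_area = file.path(dir, "truth_area.csv"),
    truth_class_counts = file.path(dir, "truth_class_counts.csv")
  )
  write_key(crop_key, paths[["crop_key"]], "crop")
  write_key(compound_key, paths[["compound_key"]], "compound")
  # landcover key: component_groups is still the raw semicolon string here
  readr::write_csv(landcover_key, paths[["landcover_key"]], progress = FALSE)
  readr::write_csv(use$use, paths[["use"]], progress = FALSE)
  area_rec <- area$records
  readr::write_csv(area_rec[area_rec$program == "CENSUS", ],
                   paths[["area_census"]], progress = FALSE)
  readr::write_csv(area_rec[area_rec$program == "SURVEY", ],
                   paths[["area_survey"]], progress = FALSE)
  readr::write_csv(tox$ecotox, paths[["ecotox"]], progress = FALSE)
  readr::write_csv(tox$ppdb, paths[["ppdb"]], progress = FALSE)
  write_asc(raster, paths[["landcover"]])
  class_counts <- tibble::tibble(cdl_code = as.integer(names(counts)),
                                 n_cells = as.integer(counts))
  readr::write_csv(use$truth_rates, paths[["truth_rates"]], progress = FALSE)
  readr::write_csv(true_loads, paths[["truth_loads"]], progress = FALSE)
  readr::write_csv(tox$truth, paths[["truth_ld50"]], progress = FALSE)
  readr::write_csv(area$truth_hectares, paths[["truth_area"]],
                   progress = FALSE)
  readr::write_csv(class_counts, paths[["truth_class_counts"]],
                   progress = FALSE)
  invisible(list(
    paths = paths,
    truth = list(rates = use$truth_rates, loads = true_loads,
                 ld50 = tox$truth, area = area$truth_hectares,
                 class_counts = class_counts),
    config = config
  ))
}

#' Generate paired estimates for exercising the validation machinery
#'
#' Draws reference estimates lognormally per category and produces
#' pipeline-side estimates with a controllable multiplicative bias and
#' lognormal noise, plus optional planted outlier pairs (a compound-crop
#' combination with wildly discrepant estimates, tagged in the
#' attributes so the exclusion path can be exercised).
#'
#' @param config A [sim_config()] (supplies the seed).
#' @param bias Multiplicative bias of `est_a` relative to `est_b`
#'   (1 = unbiased).
#' @param noise_sd Standard deviation of lognormal noise (0 = exact
#'   ratio `bias` everywhere).
#' @param n_outliers Number of planted outlier pairs (compound
#'   `"OUTLIER_CMPD"` in crop `"COTTON"`).
#' @param n_per_category Pairs per pesticide category.
#' @return Tibble of comparison records (`state`, `crop`, `year`,
#'   `compound`, `category`, `est_a`, `est_b`, `pct_area_treated`) with
#'   attribute `"params"` recording the generating parameters.
#' @export
generate_validation_pairs <- function(config = sim_config(), bias = 1,
                                      noise_sd = 0, n_outliers = 0,
                                      n_per_category = 100) {
  stopifnot(noise_sd >= 0)
  set.seed(config$seed + 1L)
  cats <- c("insecticide", "fungicide", "herbicide")
  n <- n_per_category * length(cats)
  est_b <- stats::rlnorm(n, log(1000), 1)
  ratio <- bias * exp(stats::rnorm(n, 0, noise_sd))
  recs <- tibble::tibble(
    state = sample(utils::head(CONTIGUOUS_STATES, config$n_states), n,
                   replace = TRUE),
    crop = sample(c("CORN", "SOYBEANS", "WHEAT", "COTTON", "RICE"), n,
                  replace = TRUE),
    year = sample(config$years, n, replace = TRUE),
    compound = sprintf("CMP_%03d", seq_len(n)),
    category = rep(cats, each = n_per_category),
    est_a = est_b * ratio,
    est_b = est_b,
    pct_area_treated = stats::runif(n, 5, 100)
  )
  if (n_outliers > 0) {
    take <- seq_len(min(n_outliers, n))
    recs$compound[take] <- "OUTLIER_CMPD"
    recs$crop[take] <- "COTTON"
    recs$est_a[take] <- recs$est_b[take] * 40
  }
  attr(recs, "params") <- list(bias = bias, noise_sd = noise_sd,
                               n_outliers = n_outliers)
  recs
}
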
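#' Read a pesticide use CSV
#'
#' Expected columns: `compound`, `state`, `usgs_crop_group`, `year`,
#' `kg_low`, `kg_high` (kg of active ingredient applied; either estimate
#' may be missing, and `kg_high >= kg_low` where both are present). The
#' low and high estimates differ in the treatment of missing values in
#' the underlying farmer survey; the pipeline defaults to the low one.
#'
#' @param path CSV path.
#' @return Tibble of use records with normalized compound names.
#' @export
read_use_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("compound", "state", "usgs_crop_group", "year", "kg_low", "kg_high")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("use file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fail_rows(!df$usgs_crop_group %in% crop_groups(), "unknown usgs_crop_group")
  both <- !is.na(df$kg_low) & !is.na(df$kg_high)
  fail_rows(both & df$kg_high < df$kg_low, "kg_high < kg_low")
  tibble::tibble(
    compound = normalize_name(df$compound),
    state = as.character(df$state),
    usgs_crop_group = df$usgs_crop_group,
    year = as.integer(df$year),
    kg_low = as.numeric(df$kg_low),
    kg_high = as.numeric(df$kg_high)
  )
}

#' Compute average application rates (kg/ha)
#'
#' Divides kg applied by crop-group area (ha) for every combination of
#' compound, state, crop group and year. Use rows whose kg estimate is
#' missing are treated as "no data" (dropped, not zero). Rows with
#' positive kg but zero or missing area have an undefined rate: they are
#' excluded from the output and returned in the `"undefined"` attribute
#' rather than silently dropped.
#'
#' @param use Use-record tibble (see [read_use_csv()]).
#' @param area Group-area tibble from [build_area()] /
#'   [aggregate_groups()].
#' @param variant `"low"` (default) or `"high"`: which kg estimate to
#'   use.
#' @return Tibble of rate records: `compound`, `state`,
#'   `usgs_crop_group`, `year`, `kg_per_ha`, `estimate_variant`; with
#'   attribute `"undefined"` holding the flagged rows.
#' @export
compute_rates <- function(use, area, variant = c("low", "high")) {
  variant <- match.arg(variant)
  kg <- if (variant == "low") use$kg_low else use$kg_high
  use <- use[!is.na(kg), , drop = FALSE]
  kg <- kg[!is.na(kg)]
  joined <- dplyr::left_join(
    dplyr::mutate(use, kg = kg),
    area[c("state", "usgs_crop_group", "year", "hectares")],
    by = c("state", "usgs_crop_group", "year")
  )
  undefined <- is.na(joined$hectares) | joined$hectares <= 0
  out <- tibble::tibble(
    compound = joined$compound[!undefined],
    state = joined$state[!undefined],
    usgs_crop_group = joined$usgs_crop_group[!undefined],
    year = joined$year[!undefined],
    kg_per_ha = joined$kg[!undefined] / joined$hectares[!undefined],
    estimate_variant = variant
  )
  flagged <- joined[undefined,
                    c("compound", "state", "usgs_crop_group", "year", "kg"),
                    drop = FALSE]
  if (nrow(flagged) > 0) {
    flagged$reason <- "zero or missing area"
    message(nrow(flagged), " use row(s) had zero/missing area; ",
            "see attr(, \"undefined\")")
  }
  attr(out, "undefined") <- tibble::as_tibble(flagged)
  out
}

#' Honey-bee lethal doses applied per hectare
#'
#' Converts an application rate to a count of honey-bee LD50 doses per
#' hectare: `rate` (kg/ha) is bridged to micrograms (factor 1e9) and
#' divided by the LD50 (micrograms per bee), so the result is the number
#' of per-bee lethal doses spread over each hectare.
#'
#' @param rate Application rate, kg/ha (vectorized).
#' @param ld50 Acute LD50, micrograms per bee (vectorized, must be
#'   positive).
#' @return Lethal doses per hectare.
#' @export
#' @examples
#' lethal_doses_per_ha(0.001, 1) # 1e6
lethal_doses_per_ha <- function(rate, ld50) {
  if (any(!is.finite(ld50) | ld50 <= 0)) {
    stop("LD50 values must be positive and finite", call. = FALSE)
  }
  (rate * 1e9) / ld50
}

#' Aggregate insecticide bee toxic load
#'
#' Filters the rate table to insecticides (per the compound key), joins
#' the consensus LD50 table, converts each compound's rate to lethal
#' doses per hectare on both toxicity bases, and sums across compounds
#' within each state, crop group and year. An insecticide present in the
#' rates but absent from the LD50 table is a pipeline-ordering error
#' (imputation guarantees full coverage) and aborts.
#'
#' Aggregate outputs are truncated at 2014 by default because
#' seed-applied pesticides -- a major contributor to bee toxic load --
#' are excluded from the source data after that year.
#'
#' @param rates Rate tibble from [compute_rates()].
#' @param ld50 Long consensus table from [build_ld50_table()].
#' @param compound_key Compound key tibble.
#' @param max_year Last year retained (default 2014); `Inf` disables
#'   truncation.
#' @return Tibble of toxic-load records: `state`, `usgs_crop_group`,
#'   `year`, `insecticide_kg_per_ha`, `lethal_doses_per_ha_contact`,
#'   `lethal_doses_per_ha_oral`, `interpolated` (all `FALSE` here).
#' @export
compute_toxic_load <- function(rates, ld50, compound_key, max_year = 2014) {
  ins <- compound_key$usgs_name[compound_key$category == "insecticide"]
  r <- rates[rates$compound %in% ins & rates$year <= max_year, , drop = FALSE]
  wide <- tidyr::pivot_wider(
    ld50[c("compound", "route", "ld50_ug_per_bee")],
    names_from = "route", values_from = "ld50_ug_per_bee"
  )
  r <- dplyr::left_join(r, wide, by = "compound")
  if (any(is.na(r$contact)) || any(is.na(r$oral))) {
    stop("insecticide(s) missing from the LD50 table: ",
         paste(unique(r$compound[is.na(r$contact) | is.na(r$oral)]),
               collapse = ", "),
         " (run impute_unresolved/build_ld50_table first)", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(r, .data$state, .data$usgs_crop_group, .data$year),
    insecticide_kg_per_ha = sum(.data$kg_per_ha),
    lethal_doses_per_ha_contact =
      sum(lethal_doses_per_ha(.data$kg_per_ha, .data$contact)),
    lethal_doses_per_ha_oral =
      sum(lethal_doses_per_ha(.data$kg_per_ha, .data$oral)),
    .groups = "drop"
  )
  out$interpolated <- FALSE
  dplyr::arrange(out, .data$state, .data$usgs_crop_group, .data$year)
}

#' Fill interior gaps in the toxic-load panel
#'
#' Within each state and crop-group series, missing years strictly
#' between observed years are filled by linear interpolation,
#' independently for each measure (kg/ha, contact doses/ha, oral
#' doses/ha). Years outside the observed span remain absent. Filled
#' rows are marked `interpolated = TRUE`.
#'
#' @param panel Toxic-load tibble from [compute_toxic_load()].
#' @return Toxic-load tibble with interior gaps filled.
#' @export
interpolate_loads <- function(panel) {
  measures <- c("insecticide_kg_per_ha", "lethal_doses_per_ha_contact",
                "lethal_doses_per_ha_oral")
  out <- dplyr::bind_rows(lapply(
    split(panel, paste(panel$state, panel$usgs_crop_group, sep = "\r")),
    function(one) {
      years <- seq(min(one$year), max(one$year))
      base <- tibble::tibble(state = one$state[1],
                             usgs_crop_group = one$usgs_crop_group[1],
                             year = years)
      filled_any <- rep(FALSE, length(years))
      for (m in measures) {
        obs <- one[!is.na(one[[m]]), c("year", m)]
        names(obs) <- c("year", "value")
        fit <- interpolate_series(obs, years = years)
        base[[m]] <- fit$value
        filled_any <- filled_any | fit$interpolated |
          (!years %in% one$year & !is.na(fit$value))
      }
      base$interpolated <- filled_any
      # drop years where nothing could be filled at all
      keep <- rowSums(!is.na(base[measures])) > 0
      base[keep, , drop = FALSE]
    }))
  dplyr::arrange(out, .data$state, .data$usgs_crop_group, .data$year)
}
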
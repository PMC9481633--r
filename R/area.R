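#' International acre in hectares
#'
#' Conversion constant applied everywhere acreage is converted:
#' 1 acre = 0.40468564224 ha.
#' @export
ACRES_TO_HECTARES <- 0.40468564224

#' Read a Quick-Stats-shaped acreage CSV
#'
#' Expected columns: `program` (`CENSUS` or `SURVEY`), `state`,
#' `commodity` (the crop name/data item), `year`, `value` (acres).
#'
#' @param path CSV path.
#' @return Tibble of area records: `state`, `crop` (normalized), `year`,
#'   `area`, `unit = "acres"`, `source` (`census`/`survey`).
#' @export
read_area_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("program", "state", "commodity", "year", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("area file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  program <- tolower(df$program)
  fail_rows(!program %in% c("census", "survey"), "unknown program")
  fail_rows(!is.finite(df$value) | df$value < 0, "negative or missing area")
  tibble::tibble(
    state = as.character(df$state),
    crop = normalize_name(df$commodity),
    year = as.integer(df$year),
    area = as.numeric(df$value),
    unit = "acres",
    source = program
  )
}

check_source_duplicates <- function(records, label) {
  key <- paste(records$state, records$crop, records$year, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (!any(dup)) return(unique(records))
  conflict <- stats::aggregate(records$area[dup], by = list(key = key[dup]),
                               FUN = function(v) length(unique(v)) > 1)
  if (any(conflict$x)) {
    stop("conflicting duplicate rows in ", label, " source for: ",
         paste(gsub("\r", "/", conflict$key[conflict$x]), collapse = "; "),
         call. = FALSE)
  }
  unique(records)
}

#' Choose between census and survey acreage
#'
#' Produces one record per state, crop and year from the two acreage
#' sources: in census years (1997, 2002, 2007, 2012, 2017) the census
#' value wins wherever the census reports that state and crop, even when
#' a survey value coexists; elsewhere the survey value is used.
#' Conflicting duplicate rows within one source (same state/crop/year,
#' different value) abort; exact duplicates are collapsed.
#'
#' @param census,survey Area-record tibbles (see [read_area_csv()]),
#'   already filtered to state-level contiguous-US data from 1997 on.
#' @return Combined area-record tibble with a single row per
#'   state/crop/year.
#' @export
select_area_source <- function(census, survey) {
  census <- check_source_duplicates(census, "census")
  survey <- check_source_duplicates(survey, "survey")
  if (any(!census$year %in% CENSUS_YEARS)) {
    stop("census records found outside census years: ",
         paste(sort(unique(census$year[!census$year %in% CENSUS_YEARS])),
               collapse = ", "), call. = FALSE)
  }
  census$source <- "census"
  survey$source <- "survey"
  key_c <- paste(census$state, census$crop, census$year, sep = "\r")
  key_s <- paste(survey$state, survey$crop, survey$year, sep = "\r")
  out <- dplyr::bind_rows(census, survey[!key_s %in% key_c, , drop = FALSE])
  dplyr::arrange(out, .data$state, .data$crop, .data$year)
}

#' Linearly interpolate interior gaps in an annual series
#'
#' Fills every missing year strictly between two observed years by
#' linear interpolation between the nearest bracketing observations.
#' Years before the first or after the last observation are never
#' filled (no extrapolation). Zero observations are valid anchors.
#'
#' @param series A tibble/data.frame with columns `year` and `value`, or
#'   a numeric vector named by year. Observed years only.
#' @param years Optional integer vector of years to cover; defaults to
#'   the full span of the observed years. Years outside the observed
#'   span are returned with `value = NA`.
#' @return Tibble with columns `year`, `value`, `interpolated`
#'   (logical; `NA` values carry `interpolated = FALSE`).
#' @export
#' @examples
#' interpolate_series(c(`1997` = 10, `2002` = 20))
interpolate_series <- function(series, years = NULL) {
  if (is.numeric(series) && !is.null(names(series))) {
    series <- tibble::tibble(year = as.integer(names(series)),
                             value = as.numeric(series))
  }
  stopifnot(all(c("year", "value") %in% names(series)))
  obs <- series[!is.na(series$value), , drop = FALSE]
  obs <- obs[order(obs$year), , drop = FALSE]
  if (anyDuplicated(obs$year)) {
    stop("duplicate observed years in series", call. = FALSE)
  }
  if (is.null(years)) {
    if (nrow(obs) == 0) {
      return(tibble::tibble(year = integer(), value = numeric(),
                            interpolated = logical()))
    }
    years <- seq(min(obs$year), max(obs$year))
  }
  years <- sort(unique(as.integer(years)))
  value <- rep(NA_real_, length(years))
  hit <- match(years, obs$year)
  value[!is.na(hit)] <- obs$value[hit[!is.na(hit)]]
  gap <- is.na(value) & if (nrow(obs) >= 2) {
    years > min(obs$year) & years < max(obs$year)
  } else FALSE
  if (any(gap)) {
    value[gap] <- stats::approx(obs$year, obs$value, xout = years[gap],
                                method = "linear", rule = 1)$y
  }
  tibble::tibble(year = years, value = value,
                 interpolated = gap & !is.na(value))
}

#' Convert area records from acres to hectares
#'
#' Multiplies by the international-acre constant
#' ([ACRES_TO_HECTARES]). Applying it to records already in hectares is
#' an error (double-conversion guard).
#'
#' @param records Area-record tibble with a `unit` column.
#' @return The records with `area` in hectares and `unit = "hectares"`.
#' @export
to_hectares <- function(records) {
  if (any(records$unit != "acres")) {
    stop("records already in hectares (or unknown unit); refusing to convert",
         call. = FALSE)
  }
  records$area <- records$area * ACRES_TO_HECTARES
  records$unit <- "hectares"
  records
}

#' Sum crop areas into crop groups
#'
#' Joins area records (hectares) to the crop key and sums within state,
#' crop group and year. Rows for California use the California key
#' variant (which includes the California-only crops); all other states
#' use the national variant. Crops absent from the key are excluded and
#' reported via the `"unmatched"` attribute (and a warning).
#'
#' @param records Area-record tibble in hectares, with a `source` column
#'   (`census`/`survey`/`interpolated`).
#' @param crop_key Crop key tibble from [load_key()].
#' @param california Logical: use the California key variant (all rows)
#'   rather than the national one (rows with `california_only = FALSE`).
#' @return Tibble of group-area records: `state`, `usgs_crop_group`,
#'   `year`, `hectares`, `interpolated_fraction` (share of hectares
#'   contributed by interpolated records), with attribute `"unmatched"`
#'   listing excluded crop names.
#' @export
aggregate_groups <- function(records, crop_key, california = FALSE) {
  key <- if (california) crop_key else
    crop_key[!crop_key$california_only, , drop = FALSE]
  if (any(records$unit != "hectares")) {
    stop("aggregate_groups expects records in hectares", call. = FALSE)
  }
  joined <- dplyr::left_join(records,
                             key[c("usda_crop_name", "usgs_crop_group")],
                             by = c(crop = "usda_crop_name"))
  unmatched <- sort(unique(joined$crop[is.na(joined$usgs_crop_group)]))
  if (length(unmatched) > 0) {
    warning("excluding crops absent from the ",
            if (california) "California" else "national", " crop key: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
    joined <- joined[!is.na(joined$usgs_crop_group), , drop = FALSE]
  }
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$state, .data$usgs_crop_group, .data$year),
    hectares = sum(.data$area),
    interpolated_fraction = if (sum(.data$area) > 0) {
      sum(.data$area[.data$source == "interpolated"]) / sum(.data$area)
    } else 0,
    .groups = "drop"
  )
  attr(out, "unmatched") <- unmatched
  out
}

#' Build the harmonized crop-group area panel
#'
#' Full acreage processing: the census/survey records are split into
#' California and the other states (processed against the matching key
#' variant), the census-wins selection is applied, interior gaps in each
#' state-crop series are filled by linear interpolation, areas are
#' converted to hectares and summed by crop group, and the two panels
#' are recombined.
#'
#' @param census,survey Area-record tibbles (see [read_area_csv()]).
#' @param crop_key Crop key tibble.
#' @param years Years the panel may cover (default 1997--2017); records
#'   outside are dropped.
#' @return Group-area tibble as from [aggregate_groups()].
#' @export
build_area <- function(census, survey, crop_key, years = 1997:2017) {
  census <- census[census$year %in% years, , drop = FALSE]
  survey <- survey[survey$year %in% years, , drop = FALSE]
  one_side <- function(states, california) {
    cen <- census[census$state %in% states, , drop = FALSE]
    sur <- survey[survey$state %in% states, , drop = FALSE]
    if (nrow(cen) + nrow(sur) == 0) return(NULL)
    sel <- select_area_source(cen, sur)
    filled <- dplyr::bind_rows(lapply(
      split(sel, paste(sel$state, sel$crop, sep = "\r")),
      function(one) {
        fit <- interpolate_series(
          tibble::tibble(year = one$year, value = one$area))
        fit <- fit[!is.na(fit$value), , drop = FALSE]
        src <- one$source[match(fit$year, one$year)]
        src[fit$interpolated] <- "interpolated"
        tibble::tibble(state = one$state[1], crop = one$crop[1],
                       year = fit$year, area = fit$value, unit = "acres",
                       source = src)
      }))
    aggregate_groups(to_hectares(filled), crop_key, california = california)
  }
  states <- unique(c(census$state, survey$state))
  out <- dplyr::bind_rows(
    one_side(setdiff(states, "CA"), california = FALSE),
    one_side(intersect(states, "CA"), california = TRUE)
  )
  dplyr::arrange(out, .data$state, .data$usgs_crop_group, .data$year)
}
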
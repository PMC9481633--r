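#' Read a honey-bee toxicity endpoint export
#'
#' Reads an endpoint table exported from either of the two toxicity
#' sources and standardizes it to the internal endpoint representation.
#' Exposure durations reported in hours are converted to days (48 h =
#' 2 d) before any filtering, since the sources mix units.
#'
#' Expected columns: `casrn`, `route` (`contact`/`oral`/`other`),
#' `value_ug_per_bee` (positive, micrograms per bee), `qualifier`
#' (`point`, `greater_than`, `less_than`), `regulatory` (logical: US or
#' EU regulatory provenance), `exposure_duration`, `duration_unit`
#' (`days` or `hours`), `life_stage` (`adult`/`larva`/`other`).
#'
#' @param path CSV path.
#' @param source `"ecotox"` or `"ppdb"`, recorded as provenance.
#' @return Tibble of standardized toxicity endpoints with columns
#'   `casrn`, `route`, `value_ug_per_bee`, `qualifier`, `regulatory`,
#'   `exposure_days`, `life_stage`, `source`.
#' @export
read_endpoints <- function(path, source = c("ecotox", "ppdb")) {
  source <- match.arg(source)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("casrn", "route", "value_ug_per_bee", "qualifier", "regulatory",
            "exposure_duration", "duration_unit", "life_stage")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("endpoint file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_unit <- !df$duration_unit %in% c("days", "hours")
  fail_rows(bad_unit, "unknown duration_unit")
  days <- ifelse(df$duration_unit == "hours",
                 df$exposure_duration / 24, df$exposure_duration)
  fail_rows(!df$qualifier %in% c("point", "greater_than", "less_than"),
            "unknown qualifier")
  fail_rows(!df$route %in% c("contact", "oral", "other"), "unknown route")
  fail_rows(!df$life_stage %in% c("adult", "larva", "other"),
            "unknown life_stage")
  fail_rows(!is.finite(df$value_ug_per_bee) | df$value_ug_per_bee <= 0,
            "non-positive endpoint value")
  fail_rows(!is.finite(days) | days <= 0, "non-positive exposure duration")
  tibble::tibble(
    casrn = as.character(df$casrn),
    route = df$route,
    value_ug_per_bee = as.numeric(df$value_ug_per_bee),
    qualifier = df$qualifier,
    regulatory = as.logical(df$regulatory),
    exposure_days = as.numeric(days),
    life_stage = df$life_stage,
    source = source
  )
}

#' Retain acute, adult, contact/oral endpoints
#'
#' Keeps only records representing acute exposure (4 days or less) of
#' adult bees by the contact or oral route; everything else (larval
#' assays, chronic exposures, other routes) is discarded. Empty output
#' is legal.
#'
#' @param endpoints Endpoint tibble (see [read_endpoints()]).
#' @return Filtered endpoint tibble.
#' @export
filter_acute_adult <- function(endpoints) {
  dplyr::filter(endpoints,
                .data$exposure_days <= 4,
                .data$life_stage == "adult",
                .data$route %in% c("contact", "oral"))
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Resolve a consensus LD50 for one compound and route
#'
#' Applies the preference hierarchy used to collapse heterogeneous
#' endpoints into a single acute LD50 (micrograms per bee):
#'
#' 1. Point estimates always beat censored bounds. Among points,
#'    regulatory-provenance estimates are preferred when any exist; the
#'    consensus is the geometric mean of the preferred point tier.
#' 2. With no points, "less than" bounds resolve to their minimum
#'    (`bound_min`); otherwise "greater than" bounds resolve to their
#'    maximum (`bound_max`). When both bound directions coexist the
#'    "less than" minimum wins (the conservative, more-toxic reading);
#'    such rows are flagged via the `mixed_bounds` column.
#' 3. With no usable endpoints the compound is unresolved (`NULL`).
#'
#' @param endpoints Acute/adult-filtered endpoint tibble for a single
#'   compound (any mix of routes; the requested route is selected here).
#' @param route `"contact"` or `"oral"`.
#' @return A one-row tibble with `route`, `ld50_ug_per_bee`, `basis`
#'   (`point_consensus`, `bound_min` or `bound_max`),
#'   `n_endpoints_used`, `mixed_bounds`; or `NULL` if unresolved.
#' @export
#' @examples
#' eps <- tibble::tibble(
#'   route = "contact", value_ug_per_bee = c(1, 100),
#'   qualifier = "point", regulatory = FALSE,
#'   exposure_days = 2, life_stage = "adult")
#' consensus_for_compound(eps, "contact")$ld50_ug_per_bee # 10
consensus_for_compound <- function(endpoints, route = c("contact", "oral")) {
  route <- match.arg(route)
  eps <- endpoints[endpoints$route == route, , drop = FALSE]
  if (nrow(eps) == 0) return(NULL)
  if (any(!is.finite(eps$value_ug_per_bee) | eps$value_ug_per_bee <= 0)) {
    stop("non-positive LD50 endpoint value", call. = FALSE)
  }
  res <- function(value, basis, n, mixed = FALSE) {
    tibble::tibble(route = route, ld50_ug_per_bee = value, basis = basis,
                   n_endpoints_used = as.integer(n), mixed_bounds = mixed)
  }
  points <- eps[eps$qualifier == "point", , drop = FALSE]
  if (nrow(points) > 0) {
    tier <- if (any(points$regulatory)) {
      points[points$regulatory, , drop = FALSE]
    } else {
      points
    }
    return(res(geometric_mean(tier$value_ug_per_bee), "point_consensus",
               nrow(tier)))
  }
  lt <- eps$value_ug_per_bee[eps$qualifier == "less_than"]
  gt <- eps$value_ug_per_bee[eps$qualifier == "greater_than"]
  if (length(lt) > 0) {
    return(res(min(lt), "bound_min", length(lt), mixed = length(gt) > 0))
  }
  if (length(gt) > 0) {
    return(res(max(gt), "bound_max", length(gt)))
  }
  NULL
}

#' Impute LD50s for unresolved compounds
#'
#' Compounds without any usable endpoint for a route receive the median
#' of the resolved LD50 values in their mode-of-action group
#' (`basis = "moa_median"`). Compounds whose group has no resolved
#' member receive the median over all resolved insecticides
#' (`basis = "global_median"`); if no insecticide is resolved the median
#' over all resolved compounds is used. Medians use the standard
#' midpoint-of-the-middle-two convention for even counts.
#'
#' @param consensus Tibble with columns `compound`, `route`,
#'   `ld50_ug_per_bee`, `basis`, `n_endpoints_used` holding resolved
#'   rows only (as produced by [consensus_for_compound()] per compound).
#' @param compound_key Compound key tibble (see [load_key()]); output
#'   covers every compound in it.
#' @param route `"contact"` or `"oral"`; only rows of this route are
#'   used and produced.
#' @return Complete consensus tibble, one row per key compound, sorted
#'   by compound name.
#' @export
impute_unresolved <- function(consensus, compound_key,
                              route = c("contact", "oral")) {
  route <- match.arg(route)
  resolved <- consensus[consensus$route == route &
                          !is.na(consensus$ld50_ug_per_bee), , drop = FALSE]
  if (nrow(resolved) == 0) {
    stop("cannot impute from empty set: no resolved LD50 values for route ",
         route, call. = FALSE)
  }
  key <- compound_key[order(compound_key$usgs_name), , drop = FALSE]
  resolved <- dplyr::left_join(
    resolved,
    key[c("usgs_name", "moa_group", "category")],
    by = c(compound = "usgs_name")
  )
  global_pool <- resolved$ld50_ug_per_bee[resolved$category == "insecticide"]
  if (length(global_pool) == 0) global_pool <- resolved$ld50_ug_per_bee
  rows <- lapply(seq_len(nrow(key)), function(i) {
    cmp <- key$usgs_name[i]
    hit <- resolved[resolved$compound == cmp, , drop = FALSE]
    if (nrow(hit) == 1) {
      return(hit[c("compound", "route", "ld50_ug_per_bee", "basis",
                   "n_endpoints_used")])
    }
    pool <- resolved$ld50_ug_per_bee[resolved$moa_group == key$moa_group[i]]
    if (length(pool) > 0) {
      value <- stats::median(pool)
      basis <- "moa_median"
    } else {
      value <- stats::median(global_pool)
      basis <- "global_median"
    }
    tibble::tibble(compound = cmp, route = route, ld50_ug_per_bee = value,
                   basis = basis, n_endpoints_used = 0L)
  })
  dplyr::bind_rows(rows)
}

#' Build the full consensus LD50 table from raw endpoint exports
#'
#' End-to-end toxicity processing: reads the two endpoint exports, maps
#' endpoints to compound names through the CAS crosswalk (endpoints whose
#' CAS number is absent from the key are excluded with a warning),
#' standardizes and filters to acute adult contact/oral records, resolves
#' a consensus per compound and route, and imputes the remainder so that
#' every compound in the key carries both a contact and an oral value.
#'
#' @param ecotox,ppdb CSV paths (or pre-read tibbles in the
#'   [read_endpoints()] output shape) for the two sources.
#' @param compound_key Compound key tibble from [load_key()].
#' @return Long tibble, one row per compound and route: `compound`,
#'   `casrn`, `category`, `moa_group`, `route`, `ld50_ug_per_bee`,
#'   `basis`, `n_endpoints_used`.
#' @export
build_ld50_table <- function(ecotox, ppdb, compound_key) {
  if (is.character(ecotox)) ecotox <- read_endpoints(ecotox, "ecotox")
  if (is.character(ppdb)) ppdb <- read_endpoints(ppdb, "ppdb")
  eps <- dplyr::bind_rows(ecotox, ppdb)
  eps <- dplyr::left_join(eps, compound_key[c("usgs_name", "casrn")],
                          by = "casrn")
  orphan <- is.na(eps$usgs_name)
  if (any(orphan)) {
    warning("excluding ", sum(orphan),
            " endpoint(s) with CASRN absent from the compound key: ",
            paste(unique(eps$casrn[orphan]), collapse = ", "), call. = FALSE)
    eps <- eps[!orphan, , drop = FALSE]
  }
  eps <- filter_acute_adult(eps)
  out <- lapply(c("contact", "oral"), function(rt) {
    resolved <- dplyr::bind_rows(lapply(
      split(eps, eps$usgs_name),
      function(one) {
        r <- consensus_for_compound(one, rt)
        if (is.null(r)) return(NULL)
        dplyr::bind_cols(tibble::tibble(compound = one$usgs_name[1]),
                         r[c("route", "ld50_ug_per_bee", "basis",
                             "n_endpoints_used")])
      }))
    if (nrow(resolved) == 0) {
      resolved <- tibble::tibble(compound = character(), route = character(),
                                 ld50_ug_per_bee = numeric(),
                                 basis = character(),
                                 n_endpoints_used = integer())
    }
    impute_unresolved(resolved, compound_key, rt)
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::left_join(
    out, compound_key[c("usgs_name", "casrn", "category", "moa_group")],
    by = c(compound = "usgs_name")
  )
  dplyr::arrange(
    out[c("compound", "casrn", "category", "moa_group", "route",
          "ld50_ug_per_bee", "basis", "n_endpoints_used")],
    .data$compound, .data$route
  )
}

#' Write the consensus LD50 table as a wide CSV
#'
#' One row per compound with paired contact/oral values and their bases,
#' the shape most convenient for joining to use data by compound.
#'
#' @param ld50 Long consensus table from [build_ld50_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ld50_table <- function(ld50, path) {
  wide <- tidyr::pivot_wider(
    ld50,
    id_cols = c("compound", "casrn", "category", "moa_group"),
    names_from = "route",
    values_from = c("ld50_ug_per_bee", "basis", "n_endpoints_used"),
    names_glue = "{route}_{.value}"
  )
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}
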
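#' Crop groups used by the pesticide use survey
#'
#' The pesticide use data are aggregated to ten crops or crop groups.
#' Every crosswalk key and every downstream panel is keyed on this
#' controlled vocabulary.
#'
#' @return Character vector of the ten group identifiers.
#' @export
#' @examples
#' crop_groups()
crop_groups <- function() {
  c("alfalfa", "corn", "cotton", "orchards_grapes", "other_crops",
    "pasture_hay", "rice", "soybeans", "vegetables_fruit", "wheat")
}

#' Crop groups carrying a crop-specific (not pooled) use estimate
#'
#' Corn, cotton, soybeans, alfalfa, wheat and rice are surveyed as single
#' crops; the remaining groups pool several crops, so their estimates are
#' weighted group averages. Used by [coverage_summary()].
#'
#' @return Character vector, a subset of [crop_groups()].
#' @export
crop_specific_groups <- function() {
  c("alfalfa", "corn", "cotton", "rice", "soybeans", "wheat")
}

#' Honey bee worker body mass, mg
#'
#' Documented constant for users wishing to rescale lethal-dose units to
#' other bee species by body weight. It is exposed for reference only and
#' is never applied anywhere in the pipeline.
#' @export
HONEY_BEE_WORKER_MG <- 120

# years in which the agricultural census is conducted
CENSUS_YEARS <- c(1997L, 2002L, 2007L, 2012L, 2017L)

#' Normalize a join key
#'
#' All joins across the source vocabularies (crop names, compound names)
#' are performed on upper-cased, trimmed names with internal whitespace
#' collapsed, because the source datasets differ in case and spacing.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_name("  Wheat,   Winter ")
normalize_name <- function(x) {
  toupper(gsub("\\s+", " ", trimws(x)))
}

#' CAS registry number check digit
#'
#' The check digit of a CAS number is the weighted sum of the preceding
#' digits (weights 1, 2, ... from the right) modulo 10.
#'
#' @param casrn Character vector of CAS numbers (`dddddd-dd-d`).
#' @return Integer vector of expected check digits (`NA` if malformed).
#' @export
#' @examples
#' cas_check_digit("138261-41-3") # 3
cas_check_digit <- function(casrn) {
  vapply(casrn, function(x) {
    digits <- gsub("-", "", x)
    if (!grepl("^[0-9]{4,10}$", digits)) return(NA_integer_)
    d <- as.integer(strsplit(digits, "")[[1]])
    body <- rev(d[-length(d)])
    as.integer(sum(body * seq_along(body)) %% 10L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Validate CAS registry numbers
#'
#' Checks both the `d+-dd-d` format and the check digit.
#'
#' @param casrn Character vector.
#' @return Logical vector.
#' @export
#' @examples
#' cas_is_valid(c("138261-41-3", "138261-41-4"))
cas_is_valid <- function(casrn) {
  ok_format <- grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", casrn)
  check <- cas_check_digit(casrn)
  last <- suppressWarnings(as.integer(substr(casrn, nchar(casrn), nchar(casrn))))
  ok_format & !is.na(check) & check == last
}

key_columns <- list(
  crop = c("usda_crop_name", "usgs_crop_group", "area_item", "california_only"),
  compound = c("usgs_name", "casrn", "category", "moa_group", "usda_name"),
  landcover = c("cdl_code", "cdl_name", "kind", "component_groups",
                "surveyed_components", "california_variant")
)

#' Load a crosswalk key
#'
#' Reads one of the three key families that join the source datasets:
#'
#' * `"crop"`: USDA crop names to the ten crop groups, with the acreage
#'   data item used for each crop (`harvested_acres` for annual and hay
#'   crops, `bearing_nonbearing_acres` for tree crops) and a flag for
#'   crops only surveyed in California.
#' * `"compound"`: pesticide active-ingredient names to CAS registry
#'   numbers, pesticide category (insecticide/fungicide/herbicide/other)
#'   and resistance-committee mode-of-action group, plus the optional
#'   name used by the independent validation survey.
#' * `"landcover"`: land-cover class codes to crop groups, including
#'   double-crop classes (two component groups, pesticide use assumed
#'   additive), unsurveyed crops and noncrop classes. In
#'   `component_groups` (semicolon-separated) the first
#'   `surveyed_components` entries are the surveyed ones.
#'
#' Rows violating the key invariants (unknown enum values, invalid CAS
#' check digits, duplicated primary names, malformed double-crop rows)
#' abort with an informative error.
#'
#' @param path Path to a UTF-8 comma-delimited CSV with a single header
#'   row; required columns per kind are listed above.
#' @param key_kind One of `"crop"`, `"compound"`, `"landcover"`.
#' @return A tibble of validated key records; `component_groups` is a
#'   list-column of character vectors for landcover keys.
#' @export
load_key <- function(path, key_kind = c("crop", "compound", "landcover")) {
  key_kind <- match.arg(key_kind)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- key_columns[[key_kind]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("key file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  switch(key_kind,
    crop = validate_crop_key(df),
    compound = validate_compound_key(df),
    landcover = validate_landcover_key(df)
  )
}

fail_rows <- function(bad, what) {
  if (any(bad)) {
    stop(what, " in row(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
}

validate_crop_key <- function(df) {
  df$usda_crop_name <- normalize_name(df$usda_crop_name)
  df$california_only <- as.logical(df$california_only)
  fail_rows(!df$usgs_crop_group %in% crop_groups(),
            "unknown usgs_crop_group")
  fail_rows(!df$area_item %in% c("harvested_acres", "bearing_nonbearing_acres"),
            "unknown area_item")
  fail_rows(is.na(df$california_only), "missing california_only")
  # one group per crop name within each key variant
  dup <- duplicated(df[c("usda_crop_name", "california_only")])
  if (any(dup)) {
    stop("duplicate usda_crop_name in crop key: ",
         paste(unique(df$usda_crop_name[dup]), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

validate_compound_key <- function(df) {
  df$usgs_name <- normalize_name(df$usgs_name)
  dup <- duplicated(df$usgs_name)
  if (any(dup)) {
    stop("duplicate usgs_name in compound key: ",
         paste(unique(df$usgs_name[dup]), collapse = ", "), call. = FALSE)
  }
  fail_rows(!df$category %in% c("insecticide", "fungicide", "herbicide", "other"),
            "unknown category")
  has_cas <- !is.na(df$casrn) & nzchar(df$casrn)
  bad_cas <- has_cas & !cas_is_valid(df$casrn)
  if (any(bad_cas)) {
    stop("invalid CASRN (format or check digit) for: ",
         paste(df$usgs_name[bad_cas], collapse = ", "), call. = FALSE)
  }
  df$usda_name <- ifelse(is.na(df$usda_name) | !nzchar(df$usda_name),
                         NA_character_, normalize_name(df$usda_name))
  tibble::as_tibble(df)
}

validate_landcover_key <- function(df) {
  df$cdl_code <- as.integer(df$cdl_code)
  fail_rows(is.na(df$cdl_code), "missing cdl_code")
  fail_rows(!df$kind %in% c("single_crop", "double_crop", "noncrop"),
            "unknown kind")
  df$california_variant <- as.logical(df$california_variant)
  comps <- strsplit(ifelse(is.na(df$component_groups), "", df$component_groups),
                    ";", fixed = TRUE)
  comps <- lapply(comps, function(x) x[nzchar(x)])
  n_comp <- lengths(comps)
  fail_rows(df$kind == "double_crop" & n_comp != 2L,
            "double_crop rows need exactly 2 component_groups")
  fail_rows(df$kind == "noncrop" & n_comp != 0L,
            "noncrop rows must have no component_groups")
  fail_rows(df$kind == "single_crop" & n_comp > 1L,
            "single_crop rows may have at most 1 component group")
  df$surveyed_components <- as.integer(df$surveyed_components)
  fail_rows(is.na(df$surveyed_components) | df$surveyed_components < 0L |
              df$surveyed_components > n_comp,
            "surveyed_components must be between 0 and the number of components")
  dup <- duplicated(df[c("cdl_code", "california_variant")])
  if (any(dup)) {
    stop("duplicate cdl_code in landcover key: ",
         paste(unique(df$cdl_code[dup]), collapse = ", "), call. = FALSE)
  }
  df$component_groups <- comps
  tibble::as_tibble(df)
}

#' Write a crosswalk key back to CSV
#'
#' Inverse of [load_key()]; reloading the written file yields identical
#' records.
#'
#' @param key A key tibble from [load_key()] (or built in code).
#' @param path Output CSV path.
#' @param key_kind One of `"crop"`, `"compound"`, `"landcover"`.
#' @return `path`, invisibly.
#' @export
write_key <- function(key, path, key_kind = c("crop", "compound", "landcover")) {
  key_kind <- match.arg(key_kind)
  out <- key
  if (key_kind == "landcover") {
    out$component_groups <- vapply(out$component_groups,
                                   paste, character(1), collapse = ";")
  }
  readr::write_csv(out[key_columns[[key_kind]]], path, progress = FALSE)
  invisible(path)
}

#' Cross-check the loaded keys against each other
#'
#' Reports (without erroring) every inconsistency between the key
#' families: compounds lacking a CAS number or a validation-survey name,
#' crops lacking a crop group, and land-cover classes whose component
#' groups are not among the ten crop groups. An empty report means the
#' crosswalk is internally consistent.
#'
#' @param crop_key,compound_key,landcover_key Key tibbles from
#'   [load_key()]; any may be `NULL` to skip its checks.
#' @return A tibble with columns `key`, `identifier`, `issue`; zero rows
#'   if and only if the keys are consistent.
#' @export
validate_crosswalk <- function(crop_key = NULL, compound_key = NULL,
                               landcover_key = NULL) {
  issues <- list()
  add <- function(key, identifier, issue) {
    tibble::tibble(key = key, identifier = as.character(identifier),
                   issue = issue)
  }
  if (!is.null(compound_key)) {
    no_cas <- is.na(compound_key$casrn) | !nzchar(compound_key$casrn)
    if (any(no_cas)) {
      issues <- c(issues, list(add("compound", compound_key$usgs_name[no_cas],
                                   "missing casrn")))
    }
    no_usda <- is.na(compound_key$usda_name)
    if (any(no_usda)) {
      issues <- c(issues, list(add("compound", compound_key$usgs_name[no_usda],
                                   "missing usda_name")))
    }
  }
  if (!is.null(crop_key)) {
    no_grp <- is.na(crop_key$usgs_crop_group)
    if (any(no_grp)) {
      issues <- c(issues, list(add("crop", crop_key$usda_crop_name[no_grp],
                                   "missing usgs_crop_group")))
    }
  }
  if (!is.null(landcover_key)) {
    bad <- vapply(landcover_key$component_groups,
                  function(g) any(!g %in% crop_groups()), logical(1))
    if (any(bad)) {
      issues <- c(issues, list(add("landcover", landcover_key$cdl_code[bad],
                                   "component group not among the ten crop groups")))
    }
  }
  if (length(issues) == 0) {
    return(tibble::tibble(key = character(), identifier = character(),
                          issue = character()))
  }
  dplyr::bind_rows(issues)
}
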
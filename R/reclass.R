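#' In-memory raster grid
#'
#' Lightweight container for a single-band regular grid: a numeric (or
#' integer) matrix plus georeferencing metadata (lower-left corner
#' coordinates, square cell size, optional CRS string) and a nodata
#' sentinel. Row 1 of the matrix is the top (northernmost) row, as in
#' the on-disk raster formats.
#'
#' @param values Numeric/integer matrix of cell values (`NA` = nodata).
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length (map units; 30 mirrors the nominal
#'   land-cover product resolution).
#' @param crs Optional CRS description string, passed through untouched.
#' @param nodata Sentinel written for `NA` cells on disk.
#' @return An object of class `beeload_raster`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 30,
                        crs = NA_character_, nodata = -9999) {
  stopifnot(is.matrix(values))
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         crs = crs, nodata = nodata),
    class = "beeload_raster"
  )
}

#' @export
print.beeload_raster <- function(x, ...) {
  cat("<beeload_raster> ", nrow(x$values), " x ", ncol(x$values),
      " cells, cellsize ", x$cellsize,
      ", origin (", x$xll, ", ", x$yll, ")\n", sep = "")
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat("  values: min ", format(min(v)), ", max ", format(max(v)),
        ", NA cells: ", sum(is.na(x$values)), "\n", sep = "")
  } else {
    cat("  all cells NA\n")
  }
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text `.asc` raster interchange format (6-line
#' header: `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`, then one row of cell values per line, north first).
#'
#' @param path `.asc` file path.
#' @return A [raster_grid()] object; nodata cells become `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 0
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (suppressWarnings(!is.na(as.numeric(parts[1])))) break
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(header))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nodata <- if ("nodata_value" %in% names(header))
    header$nodata_value else -9999
  body <- scan(text = paste(lines[(i + 1):length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != header$ncols * header$nrows) {
    stop("ASCII grid body size mismatch in ", path, call. = FALSE)
  }
  values <- matrix(body, nrow = header$nrows, ncol = header$ncols,
                   byrow = TRUE)
  values[values == nodata] <- NA
  raster_grid(values, xll = header$xllcorner, yll = header$yllcorner,
              cellsize = header$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param raster A [raster_grid()] object.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  fmt <- function(x) format(x, scientific = FALSE, digits = 15)
  header <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", fmt(raster$xll)),
    paste("yllcorner", fmt(raster$yll)),
    paste("cellsize", fmt(raster$cellsize)),
    paste("NODATA_value", fmt(raster$nodata))
  )
  rows <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 15,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Build a land-cover reclassification table for one state-year
#'
#' Maps each land-cover class code to a predicted pesticide value from a
#' per-crop-group value map, applying the following conventions:
#'
#' * noncrop classes: `noncrop = 1`, no value;
#' * unsurveyed crop classes: `unsurveyed = 1`, no value;
#' * single-crop surveyed classes: the group's value (missing if the
#'   group has no estimate for this state-year);
#' * double-crop classes: pesticide use is assumed additive across the
#'   two component crops. For `table_kind = "aggregate"` a value is
#'   present only when both components are surveyed and have estimates;
#'   for `table_kind = "compound"` the sum of the available component
#'   estimates is used if at least one is present (a compound may be
#'   used in one crop but not the other). `unsurveyed = 0.5` marks
#'   double crops with exactly one surveyed component.
#'
#' @param values Named numeric vector or list mapping crop group to a
#'   value (kg/ha or doses/ha); groups may be absent or `NA` (missing
#'   estimate).
#' @param landcover_key Landcover key tibble from [load_key()].
#' @param table_kind `"aggregate"` (both components required) or
#'   `"compound"` (at least one component).
#' @param state,year Identifiers stamped on the rows.
#' @return Tibble of reclass rows: `state`, `year`, `cdl_code`,
#'   `cdl_name`, `value`, `unsurveyed`, `noncrop`.
#' @export
build_reclass_table <- function(values, landcover_key,
                                table_kind = c("aggregate", "compound"),
                                state = NA_character_, year = NA_integer_) {
  table_kind <- match.arg(table_kind)
  values <- unlist(values)
  bad <- setdiff(names(values), crop_groups())
  if (length(bad) > 0) {
    stop("values named by unknown crop group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  val_of <- function(g) {
    if (g %in% names(values)) unname(values[[g]]) else NA_real_
  }
  rows <- lapply(seq_len(nrow(landcover_key)), function(i) {
    kind <- landcover_key$kind[i]
    comps <- landcover_key$component_groups[[i]]
    s <- landcover_key$surveyed_components[i]
    value <- NA_real_
    unsurveyed <- 0
    noncrop <- 0
    if (kind == "noncrop") {
      noncrop <- 1
    } else if (kind == "single_crop") {
      if (s == 0) {
        unsurveyed <- 1
      } else {
        value <- val_of(comps[1])
      }
    } else { # double_crop; first s components are the surveyed ones
      unsurveyed <- 1 - s / 2
      surveyed_vals <- if (s > 0)
        vapply(comps[seq_len(s)], val_of, numeric(1)) else numeric(0)
      if (table_kind == "aggregate") {
        if (s == 2 && all(!is.na(surveyed_vals))) {
          value <- sum(surveyed_vals)
        }
      } else {
        if (any(!is.na(surveyed_vals))) {
          value <- sum(surveyed_vals, na.rm = TRUE)
        }
      }
    }
    tibble::tibble(state = state, year = year,
                   cdl_code = landcover_key$cdl_code[i],
                   cdl_name = landcover_key$cdl_name[i],
                   value = value, unsurveyed = unsurveyed, noncrop = noncrop)
  })
  dplyr::bind_rows(rows)
}

#' Coverage codes used in reclassified rasters
#'
#' @return Named integer vector mapping coverage classes to the codes
#'   written in the coverage grid.
#' @export
coverage_codes <- function() {
  c(surveyed = 1L, unsurveyed = 2L, noncrop = 3L, missing_value = 4L)
}

#' Reclassify a categorical land-cover raster into predicted loading
#'
#' Pure per-cell lookup of land-cover class codes in a reclassification
#' table. Produces a float value grid (nodata outside surveyed cells)
#' and a companion coverage grid recording, for every cell, why a value
#' is or is not present (`surveyed`, `unsurveyed`, `noncrop`,
#' `missing_value`). Georeferencing is passed through unchanged.
#'
#' @param landcover A [raster_grid()] of integer class codes.
#' @param table Reclass tibble from [build_reclass_table()] (one
#'   state-year).
#' @param strict If `TRUE` (default), class codes present in the raster
#'   but absent from the table abort with an error listing them;
#'   otherwise such cells get coverage `missing_value`.
#' @return An object of class `load_raster`: list with `value` and
#'   `coverage` [raster_grid()]s and the `coverage_codes()` legend.
#' @export
reclass_raster <- function(landcover, table, strict = TRUE) {
  codes <- landcover$values
  present <- sort(unique(as.vector(codes[!is.na(codes)])))
  unknown <- setdiff(present, table$cdl_code)
  if (length(unknown) > 0 && strict) {
    stop("land-cover code(s) absent from reclass table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- match(codes, table$cdl_code)
  value <- table$value[idx]
  unsurveyed <- table$unsurveyed[idx]
  noncrop <- table$noncrop[idx]
  cc <- coverage_codes()
  coverage <- ifelse(is.na(idx), cc[["missing_value"]],
              ifelse(noncrop == 1, cc[["noncrop"]],
              ifelse(unsurveyed == 1, cc[["unsurveyed"]],
              ifelse(is.na(value), cc[["missing_value"]],
                     cc[["surveyed"]]))))
  coverage[is.na(codes)] <- NA_integer_
  value[coverage != cc[["surveyed"]] | is.na(coverage)] <- NA_real_
  dim(value) <- dim(codes)
  dim(coverage) <- dim(codes)
  structure(
    list(
      value = raster_grid(value, xll = landcover$xll, yll = landcover$yll,
                          cellsize = landcover$cellsize, crs = landcover$crs,
                          nodata = landcover$nodata),
      coverage = raster_grid(coverage, xll = landcover$xll,
                             yll = landcover$yll,
                             cellsize = landcover$cellsize,
                             crs = landcover$crs, nodata = landcover$nodata),
      coverage_codes = cc
    ),
    class = "load_raster"
  )
}

#' @export
print.load_raster <- function(x, ...) {
  cat("<load_raster>\n value grid:\n")
  print(x$value)
  tab <- table(factor(x$coverage$values,
                      levels = x$coverage_codes,
                      labels = names(x$coverage_codes)))
  cat(" coverage:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Landscape mean of a reclassified raster
#'
#' Default: the mean predicted value over surveyed cells only (cells
#' with no estimate carry no information about use). Optionally the
#' mean over all cells with every non-surveyed cell counted as zero,
#' which instead treats "no estimate" as "no use".
#'
#' @param x A `load_raster` from [reclass_raster()].
#' @param include_nonsurveyed_as_zero Logical (default `FALSE`).
#' @return The mean, a single number.
#' @export
landscape_mean <- function(x, include_nonsurveyed_as_zero = FALSE) {
  stopifnot(inherits(x, "load_raster"))
  v <- as.vector(x$value$values)
  if (include_nonsurveyed_as_zero) {
    n <- sum(!is.na(x$coverage$values))
    if (n == 0) stop("no eligible cells", call. = FALSE)
    return(sum(v, na.rm = TRUE) / n)
  }
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    stop("no surveyed cells with values; nothing to average", call. = FALSE)
  }
  mean(v)
}

#' Survey coverage percentages for a land-cover raster
#'
#' Summarizes, by cell counts, how much of a landscape the underlying
#' pesticide use survey represents:
#'
#' * `pct_total_surveyed`: surveyed cells as a percentage of all cells;
#' * `pct_cropland_surveyed`: surveyed cells as a percentage of
#'   cropland (non-noncrop) cells;
#' * `pct_cropland_crop_specific`: cells carrying a crop-specific
#'   estimate (all component groups in [crop_specific_groups()]) as a
#'   percentage of cropland cells excluding pasture/hay.
#'
#' A cell counts as surveyed if at least one of its component crops is
#' in the survey (so half-surveyed double crops count). Cell counts
#' stand in for area, i.e. uniform cell area is assumed within the
#' raster.
#'
#' @param landcover A [raster_grid()] of class codes.
#' @param landcover_key Landcover key tibble covering every code in the
#'   raster.
#' @return Named list with the three percentages (0--100).
#' @export
coverage_summary <- function(landcover, landcover_key) {
  codes <- as.vector(landcover$values)
  codes <- codes[!is.na(codes)]
  idx <- match(codes, landcover_key$cdl_code)
  if (any(is.na(idx))) {
    stop("land-cover code(s) absent from key: ",
         paste(sort(unique(codes[is.na(idx)])), collapse = ", "),
         call. = FALSE)
  }
  kind <- landcover_key$kind[idx]
  s <- landcover_key$surveyed_components[idx]
  comps <- landcover_key$component_groups[idx]
  is_crop <- kind != "noncrop"
  is_surveyed <- is_crop & s >= 1
  specific <- vapply(comps, function(g) {
    length(g) > 0 && all(g %in% crop_specific_groups())
  }, logical(1))
  is_specific <- is_surveyed & specific
  is_pasture <- vapply(comps, function(g) identical(g, "pasture_hay"),
                       logical(1))
  n_total <- length(codes)
  n_crop <- sum(is_crop)
  n_crop_np <- sum(is_crop & !is_pasture)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(
    pct_total_surveyed = pct(sum(is_surveyed), n_total),
    pct_cropland_surveyed = pct(sum(is_surveyed), n_crop),
    pct_cropland_crop_specific = pct(sum(is_specific & !is_pasture), n_crop_np)
  )
}
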
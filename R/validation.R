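#' Relative percent difference between paired estimates
#'
#' `100 * (a - b) / ((a + b) / 2)`, bounded in \[-200, 200\] for
#' nonnegative inputs. When both estimates are zero the quantity is
#' undefined and `NA` is returned; callers exclude and count such pairs.
#'
#' @param a,b Nonnegative numeric vectors (same units).
#' @return Relative difference in percent.
#' @export
#' @examples
#' relative_difference(3, 1) # 100
#' relative_difference(0, 2) # -200
relative_difference <- function(a, b) {
  if (any(a < 0 | b < 0, na.rm = TRUE)) {
    stop("relative_difference expects nonnegative estimates", call. = FALSE)
  }
  out <- (a - b) / ((a + b) / 2) * 100
  out[a == 0 & b == 0] <- NA_real_
  out
}

#' Reference rate, Method 1: total kg over crop area
#'
#' Reconstructs a per-hectare rate for the reference survey by dividing
#' its total kg by the pipeline's crop-area estimate -- the same formula
#' as [compute_rates()], so the two estimates differ only through the
#' kg numerator.
#'
#' @param reference_kg Total kg applied (reference survey).
#' @param hectares Crop area, ha.
#' @return kg/ha; `NA` where `hectares <= 0` (excluded, reported via a
#'   message).
#' @export
method1_rate <- function(reference_kg, hectares) {
  out <- ifelse(hectares > 0, reference_kg / hectares, NA_real_)
  n_bad <- sum(!(hectares > 0))
  if (n_bad > 0) {
    message(n_bad, " record(s) with nonpositive area excluded from Method 1")
  }
  out
}

#' Reference rate, Method 2: treated-area rate times fraction treated
#'
#' Reconstructs a whole-area per-hectare rate from the reference
#' survey's rate on *treated acres* and its percent of area treated:
#' the treated-acre rate is down-weighted by the treated fraction and
#' converted acre to hectare once.
#'
#' @param rate_on_treated kg per treated acre.
#' @param pct_treated Percent of crop area treated, in \[0, 100\].
#' @return kg/ha averaged over all crop area.
#' @export
#' @examples
#' method2_rate(1, 50) # 0.5 / 0.40468564224
method2_rate <- function(rate_on_treated, pct_treated) {
  if (any(pct_treated > 100 | pct_treated < 0, na.rm = TRUE)) {
    stop("pct_treated must lie in [0, 100]", call. = FALSE)
  }
  rate_on_treated * (pct_treated / 100) / ACRES_TO_HECTARES
}

signed_rank_p <- function(x) {
  x <- x[!is.na(x) & x != 0]
  if (length(x) == 0) return(NA_real_)
  if (length(x) <= 25) {
    suppressWarnings(stats::wilcox.test(x, mu = 0, exact = TRUE)$p.value)
  } else {
    stats::wilcox.test(x, mu = 0, exact = FALSE, correct = TRUE)$p.value
  }
}

#' Cross-validation summary per pesticide category
#'
#' For paired pipeline/reference estimates, computes per category (and
#' per `comparison` label when present): the number of pairs, the
#' median and quartiles of the relative percent difference, a two-sided
#' one-sample Wilcoxon signed-rank p-value for median difference zero
#' (exact for n <= 25 and no ties, normal approximation with continuity
#' correction otherwise; zero differences dropped), the Spearman rank
#' correlation (average ranks for ties) and the Pearson correlation.
#' Known outlier pairs can be excluded up front (as the reference
#' comparison does for, e.g., one compound-crop combination with
#' irreconcilable estimates); exclusions and undefined (both-zero)
#' pairs are counted in the output.
#'
#' @param records Tibble with columns `category`, `est_a` (pipeline),
#'   `est_b` (reference); optional `compound`, `crop`, `comparison`.
#' @param exclusions Optional tibble/data.frame with columns `compound`
#'   and `crop`: matching records are removed before computation.
#' @return Tibble with one row per category (and comparison): `n`,
#'   `median_rd`, `q25_rd`, `q75_rd`, `wilcoxon_p`, `spearman`,
#'   `pearson`, `n_undefined`, `n_excluded`, `insufficient` (`TRUE`
#'   when n < 3).
#' @export
compare_category <- function(records, exclusions = NULL) {
  n_excluded <- 0L
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    if (!all(c("compound", "crop") %in% names(records))) {
      stop("exclusions require 'compound' and 'crop' columns in records",
           call. = FALSE)
    }
    drop <- paste(normalize_name(records$compound),
                  normalize_name(records$crop)) %in%
      paste(normalize_name(exclusions$compound),
            normalize_name(exclusions$crop))
    n_excluded <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  grouping <- intersect(c("category", "comparison"), names(records))
  records$rd <- relative_difference(records$est_a, records$est_b)
  out <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(grouping))),
    n = sum(!is.na(.data$rd)),
    median_rd = stats::median(.data$rd, na.rm = TRUE),
    q25_rd = unname(stats::quantile(.data$rd, 0.25, na.rm = TRUE)),
    q75_rd = unname(stats::quantile(.data$rd, 0.75, na.rm = TRUE)),
    wilcoxon_p = signed_rank_p(.data$rd),
    spearman = stats::cor(.data$est_a, .data$est_b, method = "spearman"),
    pearson = stats::cor(.data$est_a, .data$est_b, method = "pearson"),
    n_undefined = sum(is.na(.data$rd)),
    .groups = "drop"
  )
  out$n_excluded <- n_excluded
  out$insufficient <- out$n < 3
  out[out$insufficient, c("median_rd", "q25_rd", "q75_rd", "wilcoxon_p",
                          "spearman", "pearson")] <- NA_real_
  out
}

#' Agreement as a function of how widely a pesticide is used
#'
#' Bins the absolute relative difference between paired estimates by
#' percent of crop area treated, and reports a monotone-trend statistic
#' (Spearman correlation of |relative difference| with percent
#' treated). A negative trend indicates that estimates agree better for
#' widely used compounds.
#'
#' @param records Tibble with `est_a`, `est_b` and `pct_area_treated`.
#' @param breaks Bin edges on the percent-treated axis (default
#'   0-20-40-60-80-100).
#' @return List with `bins` (tibble: bin, n, median |RD|) and
#'   `trend_rho` (Spearman correlation).
#' @export
treated_fraction_trend <- function(records, breaks = seq(0, 100, by = 20)) {
  stopifnot("pct_area_treated" %in% names(records))
  abs_rd <- abs(relative_difference(records$est_a, records$est_b))
  keep <- !is.na(abs_rd) & !is.na(records$pct_area_treated)
  abs_rd <- abs_rd[keep]
  pct <- records$pct_area_treated[keep]
  bin <- cut(pct, breaks = breaks, include.lowest = TRUE)
  bins <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, abs_rd = abs_rd), .data$bin),
    n = dplyr::n(),
    median_abs_rd = stats::median(.data$abs_rd),
    .groups = "drop"
  )
  rho <- if (stats::sd(abs_rd) == 0 || stats::sd(pct) == 0) 0 else
    stats::cor(abs_rd, pct, method = "spearman")
  list(bins = bins, trend_rho = rho)
}
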
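# Brute-force oracle for the LD50 consensus rules, written as plain
# loops and kept independent of the package implementation.

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# endpoints: data.frame with route, value_ug_per_bee, qualifier,
# regulatory, exposure_days, life_stage. Returns list(value, basis) or NULL.
oracle_consensus <- function(endpoints, route) {
  keep <- c()
  for (i in seq_len(nrow(endpoints))) {
    e <- endpoints[i, ]
    if (e$exposure_days <= 4 && e$life_stage == "adult" && e$route == route) {
      keep <- c(keep, i)
    }
  }
  eps <- endpoints[keep, , drop = FALSE]
  if (nrow(eps) == 0) return(NULL)
  reg_points <- c(); all_points <- c(); lt <- c(); gt <- c()
  for (i in seq_len(nrow(eps))) {
    e <- eps[i, ]
    if (e$qualifier == "point") {
      all_points <- c(all_points, e$value_ug_per_bee)
      if (e$regulatory) reg_points <- c(reg_points, e$value_ug_per_bee)
    } else if (e$qualifier == "less_than") {
      lt <- c(lt, e$value_ug_per_bee)
    } else if (e$qualifier == "greater_than") {
      gt <- c(gt, e$value_ug_per_bee)
    }
  }
  if (length(all_points) > 0) {
    tier <- if (length(reg_points) > 0) reg_points else all_points
    return(list(value = prod(tier)^(1 / length(tier)),
                basis = "point_consensus"))
  }
  if (length(lt) > 0) return(list(value = min(lt), basis = "bound_min"))
  if (length(gt) > 0) return(list(value = max(gt), basis = "bound_max"))
  NULL
}

# Full oracle table: consensus + median imputation for every compound in
# the key, one route.
oracle_ld50_table <- function(endpoints_by_compound, compound_key, route) {
  resolved <- list()
  for (cmp in names(endpoints_by_compound)) {
    r <- oracle_consensus(endpoints_by_compound[[cmp]], route)
    if (!is.null(r)) resolved[[cmp]] <- r
  }
  out <- list()
  for (i in seq_len(nrow(compound_key))) {
    cmp <- compound_key$usgs_name[i]
    if (cmp %in% names(resolved)) {
      out[[cmp]] <- resolved[[cmp]]
      next
    }
    pool <- c()
    for (other in names(resolved)) {
      moa_other <- compound_key$moa_group[compound_key$usgs_name == other]
      if (identical(moa_other, compound_key$moa_group[i])) {
        pool <- c(pool, resolved[[other]]$value)
      }
    }
    if (length(pool) > 0) {
      out[[cmp]] <- list(value = oracle_median(pool), basis = "moa_median")
    } else {
      gp <- c()
      for (other in names(resolved)) {
        cat_other <- compound_key$category[compound_key$usgs_name == other]
        if (cat_other == "insecticide") gp <- c(gp, resolved[[other]]$value)
      }
      if (length(gp) == 0) {
        for (other in names(resolved)) gp <- c(gp, resolved[[other]]$value)
      }
      out[[cmp]] <- list(value = oracle_median(gp), basis = "global_median")
    }
  }
  out
}

# Random endpoint-set generator for oracle-equivalence testing: mixes
# point/bound qualifiers, regulatory status, routes, life stages and
# exposure durations (including decoys the acute-adult filter must drop).
random_endpoint_set <- function() {
  n <- sample(0:6, 1)
  if (n == 0) {
    return(data.frame(route = character(), value_ug_per_bee = numeric(),
                      qualifier = character(), regulatory = logical(),
                      exposure_days = numeric(), life_stage = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    route = sample(c("contact", "oral", "other"), n, replace = TRUE,
                   prob = c(0.45, 0.45, 0.1)),
    value_ug_per_bee = exp(runif(n, log(0.01), log(200))),
    qualifier = sample(c("point", "greater_than", "less_than"), n,
                       replace = TRUE),
    regulatory = sample(c(TRUE, FALSE), n, replace = TRUE),
    exposure_days = sample(c(1, 2, 4, 10), n, replace = TRUE,
                           prob = c(0.3, 0.3, 0.2, 0.2)),
    life_stage = sample(c("adult", "larva"), n, replace = TRUE,
                        prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE
  )
}

random_compound_key <- function(n_compounds) {
  tibble::tibble(
    usgs_name = sprintf("RND_%02d", seq_len(n_compounds)),
    casrn = NA_character_,
    category = sample(c("insecticide", "fungicide", "herbicide"),
                      n_compounds, replace = TRUE),
    moa_group = sample(paste0("G", 1:3), n_compounds, replace = TRUE),
    usda_name = NA_character_
  )
}
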
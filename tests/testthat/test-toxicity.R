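test_that("the acute-adult filter keeps only <=4-day adult contact/oral records", {
  eps <- make_endpoints(
    make_endpoint(exposure_days = 2),                       # keep
    make_endpoint(route = "oral", exposure_days = 10),      # chronic
    make_endpoint(life_stage = "larva"),                    # larval
    make_endpoint(life_stage = "larva", route = "oral"),    # larval
    make_endpoint(route = "other")                          # wrong route
  )
  kept <- filter_acute_adult(eps)
  expect_equal(nrow(kept), 1)
  # exactly-4-day exposures are acute; 4.5 days is not
  expect_equal(nrow(filter_acute_adult(make_endpoint(exposure_days = 4))), 1)
  expect_equal(nrow(filter_acute_adult(make_endpoint(exposure_days = 4.5))), 0)
})

test_that("hour-denominated durations convert to days before filtering", {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    casrn = "138261-41-3", route = "contact", value_ug_per_bee = 1,
    qualifier = "point", regulatory = FALSE,
    exposure_duration = c(48, 120), duration_unit = "hours",
    life_stage = "adult"), path)
  eps <- read_endpoints(path, "ecotox")
  expect_equal(eps$exposure_days, c(2, 5))
  expect_equal(nrow(filter_acute_adult(eps)), 1)
})

test_that("consensus prefers point estimates and pools them geometrically", {
  # equal points: geometric mean is the common value
  r <- consensus_for_compound(
    make_endpoints(make_endpoint(value = 4), make_endpoint(value = 4)),
    "contact")
  expect_equal(r$ld50_ug_per_bee, 4)
  expect_equal(r$basis, "point_consensus")
  # sqrt(1 * 100) = 10
  r <- consensus_for_compound(
    make_endpoints(make_endpoint(value = 1), make_endpoint(value = 100)),
    "contact")
  expect_equal(r$ld50_ug_per_bee, 10)
  # regulatory points beat non-regulatory points
  r <- consensus_for_compound(
    make_endpoints(make_endpoint(value = 2, regulatory = TRUE),
                   make_endpoint(value = 50)),
    "contact")
  expect_equal(r$ld50_ug_per_bee, 2)
  expect_equal(r$n_endpoints_used, 1L)
})

test_that("bounds are used only without points; direction picks min or max", {
  gt <- make_endpoints(
    make_endpoint(value = 10, qualifier = "greater_than"),
    make_endpoint(value = 20, qualifier = "greater_than"))
  r <- consensus_for_compound(gt, "contact")
  expect_equal(r$ld50_ug_per_bee, 20)
  expect_equal(r$basis, "bound_max")

  lt <- make_endpoints(
    make_endpoint(value = 10, qualifier = "less_than"),
    make_endpoint(value = 20, qualifier = "less_than"))
  r <- consensus_for_compound(lt, "contact")
  expect_equal(r$ld50_ug_per_bee, 10)
  expect_equal(r$basis, "bound_min")

  # a point estimate silences even a much larger bound
  r <- consensus_for_compound(
    make_endpoints(make_endpoint(value = 5),
                   make_endpoint(value = 100, qualifier = "greater_than")),
    "contact")
  expect_equal(r$ld50_ug_per_bee, 5)
  expect_equal(r$basis, "point_consensus")

  # mixed bound directions without points: less_than (more toxic) wins, flagged
  r <- consensus_for_compound(dplyr::bind_rows(gt, lt), "contact")
  expect_equal(r$ld50_ug_per_bee, 10)
  expect_equal(r$basis, "bound_min")
  expect_true(r$mixed_bounds)

  expect_null(consensus_for_compound(make_endpoint(route = "oral"), "contact"))
  expect_error(consensus_for_compound(make_endpoint(value = -1), "contact"),
               "positive")
})

test_that("adding a bound never changes a compound with a point estimate", {
  set.seed(401)
  for (i in 1:25) {
    pts <- make_endpoint(value = exp(runif(1, -3, 4)),
                         regulatory = sample(c(TRUE, FALSE), 1))
    base <- consensus_for_compound(pts, "contact")
    with_bound <- dplyr::bind_rows(
      pts,
      make_endpoint(value = exp(runif(1, -3, 6)),
                    qualifier = sample(c("greater_than", "less_than"), 1)))
    expect_identical(consensus_for_compound(with_bound, "contact"), base)
  }
})

test_that("point consensus lies within the range of the points pooled", {
  set.seed(402)
  for (i in 1:25) {
    v <- exp(runif(sample(2:5, 1), -4, 5))
    eps <- dplyr::bind_rows(lapply(v, function(x) make_endpoint(value = x)))
    r <- consensus_for_compound(eps, "contact")
    expect_gte(r$ld50_ug_per_bee, min(v))
    expect_lte(r$ld50_ug_per_bee, max(v))
  }
})

test_that("imputation fills gaps with group then global medians", {
  key <- mini_compound_key()
  resolved <- tibble::tibble(
    compound = c("ALPHA", "BETA", "GAMMA"), route = "contact",
    ld50_ug_per_bee = c(1, 2, 3), basis = "point_consensus",
    n_endpoints_used = 1L)
  out <- impute_unresolved(resolved, key, "contact")
  expect_equal(nrow(out), nrow(key))
  # DELTA sits in an empty group; only insecticides are resolved, so it
  # takes the global insecticide median
  delta <- out[out$compound == "DELTA", ]
  expect_equal(delta$ld50_ug_per_bee, 2)
  expect_equal(delta$basis, "global_median")
  # herbicides share no group with anything resolved -> global median too
  expect_equal(out$ld50_ug_per_bee[out$compound == "OMEGA"], 2)

  # odd-count group median
  key2 <- key
  key2$moa_group[key2$usgs_name == "DELTA"] <- "IRAC_1"
  out2 <- impute_unresolved(resolved, key2, "contact")
  expect_equal(out2$ld50_ug_per_bee[out2$compound == "DELTA"], 2)
  expect_equal(out2$basis[out2$compound == "DELTA"], "moa_median")

  # even-count global median = midpoint of middle two: {0.1,1,10,100} -> 5.5
  resolved4 <- tibble::tibble(
    compound = c("ALPHA", "BETA", "GAMMA", "DELTA"), route = "contact",
    ld50_ug_per_bee = c(0.1, 1, 10, 100), basis = "point_consensus",
    n_endpoints_used = 1L)
  key3 <- key
  key3$moa_group[key3$usgs_name == "OMEGA"] <- "LONELY"
  out3 <- impute_unresolved(resolved4, key3, "contact")
  expect_equal(out3$ld50_ug_per_bee[out3$compound == "OMEGA"], 5.5)

  # all compounds resolved -> identity
  all_resolved <- tibble::tibble(
    compound = key$usgs_name, route = "contact",
    ld50_ug_per_bee = seq_len(nrow(key)), basis = "point_consensus",
    n_endpoints_used = 1L)
  out4 <- impute_unresolved(all_resolved, key, "contact")
  expect_equal(out4$ld50_ug_per_bee[match(key$usgs_name, out4$compound)],
               as.numeric(seq_len(nrow(key))))

  expect_error(
    impute_unresolved(resolved[0, ], key, "contact"),
    "cannot impute from empty set")
})

test_that("imputed values are medians of observed values (membership)", {
  set.seed(403)
  for (i in 1:20) {
    key <- random_compound_key(8)
    n_res <- sample(1:6, 1)
    resolved <- tibble::tibble(
      compound = key$usgs_name[seq_len(n_res)], route = "contact",
      ld50_ug_per_bee = exp(runif(n_res, -3, 4)),
      basis = "point_consensus", n_endpoints_used = 1L)
    out <- impute_unresolved(resolved, key, "contact")
    imputed <- out[out$basis %in% c("moa_median", "global_median"), ]
    obs <- sort(resolved$ld50_ug_per_bee)
    mids <- unique(as.vector(outer(obs, obs, function(a, b) (a + b) / 2)))
    expect_true(all(imputed$ld50_ug_per_bee %in% c(obs, mids)))
  }
})

test_that("the end-to-end LD50 table matches the brute-force oracle", {
  set.seed(404)
  for (rep in 1:10) {
    key <- random_compound_key(6)
    sets <- setNames(lapply(key$usgs_name, function(x) random_endpoint_set()),
                     key$usgs_name)
    for (route in c("contact", "oral")) {
      resolved <- dplyr::bind_rows(lapply(names(sets), function(cmp) {
        r <- consensus_for_compound(
          filter_acute_adult(tibble::as_tibble(sets[[cmp]])), route)
        if (is.null(r)) return(NULL)
        dplyr::bind_cols(tibble::tibble(compound = cmp),
                         r[c("route", "ld50_ug_per_bee", "basis",
                             "n_endpoints_used")])
      }))
      oracle <- tryCatch(oracle_ld50_table(sets, key, route),
                         error = function(e) NULL)
      if (nrow(resolved) == 0) {
        expect_error(impute_unresolved(resolved, key, route))
        next
      }
      got <- impute_unresolved(resolved, key, route)
      for (cmp in key$usgs_name) {
        expect_equal(got$ld50_ug_per_bee[got$compound == cmp],
                     oracle[[cmp]]$value, tolerance = 1e-12, info = cmp)
        expect_equal(got$basis[got$compound == cmp], oracle[[cmp]]$basis,
                     info = cmp)
      }
    }
  }
})

test_that("consensus output is invariant to endpoint row order", {
  set.seed(405)
  eps <- tibble::as_tibble(random_endpoint_set())
  while (nrow(eps) < 4) eps <- tibble::as_tibble(random_endpoint_set())
  base <- consensus_for_compound(filter_acute_adult(eps), "contact")
  for (i in 1:5) {
    shuffled <- eps[sample(nrow(eps)), ]
    expect_equal(consensus_for_compound(filter_acute_adult(shuffled),
                                        "contact"), base)
  }
})

test_that("build_ld50_table covers every key compound on both routes", {
  cfg <- sim_config(seed = 21, n_states = 2, years = 1997:2000)
  dir <- withr::local_tempdir()
  b <- generate_fixture_bundle(cfg, dir)
  key <- load_key(b$paths[["compound_key"]], "compound")
  tab <- build_ld50_table(b$paths[["ecotox"]], b$paths[["ppdb"]], key)
  expect_equal(nrow(tab), 2 * nrow(key))
  expect_setequal(unique(tab$compound), key$usgs_name)
  expect_true(all(tab$ld50_ug_per_bee > 0))
  # the planted ground truth is recovered, basis included
  m <- dplyr::inner_join(tab, b$truth$ld50, by = c("compound", "route"))
  expect_equal(m$ld50_ug_per_bee.x, m$ld50_ug_per_bee.y, tolerance = 1e-12)
  expect_equal(m$basis.x, m$basis.y)
  # round-trip of the wide CSV shape
  out <- tempfile(fileext = ".csv")
  write_ld50_table(tab, out)
  wide <- readr::read_csv(out, show_col_types = FALSE)
  expect_equal(nrow(wide), nrow(key))
  expect_true(all(c("contact_ld50_ug_per_bee", "oral_ld50_ug_per_bee")
                  %in% names(wide)))
})

test_that("endpoints with unknown CAS numbers are excluded with a warning", {
  key <- tibble::tibble(usgs_name = "KNOWN", casrn = "138261-41-3",
                        category = "insecticide", moa_group = "IRAC_1",
                        usda_name = NA_character_)
  eps <- tibble::tibble(
    casrn = c("138261-41-3", "138261-41-3", "1071-83-6"),
    route = c("contact", "oral", "contact"),
    value_ug_per_bee = c(1, 3, 2), qualifier = "point", regulatory = FALSE,
    exposure_days = 2, life_stage = "adult", source = "ecotox")
  expect_warning(
    tab <- build_ld50_table(eps[0, ], eps, key),
    "absent from the compound key")
  expect_equal(tab$ld50_ug_per_bee[tab$route == "contact"], 1)
})
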
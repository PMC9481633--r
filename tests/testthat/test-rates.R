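test_that("rates divide kg by hectares and flag undefined rows", {
  area <- mini_area()
  use <- mini_use("ALPHA", kg = 50)
  out <- compute_rates(use, area)
  expect_equal(out$kg_per_ha, 0.5)
  expect_equal(compute_rates(mini_use("ALPHA", kg = 0), area)$kg_per_ha, 0)

  # one of four rows lacks area -> 3 rates + 1 flagged, not silently dropped
  use4 <- mini_use("ALPHA", groups = "corn", years = 1997:2000, kg = 10)
  use4$usgs_crop_group[4] <- "rice" # no rice area in the fixture
  expect_message(out4 <- compute_rates(use4, area), "zero/missing area")
  expect_equal(nrow(out4), 3)
  flagged <- attr(out4, "undefined")
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$usgs_crop_group, "rice")

  # zero hectares with positive kg is undefined, not infinite
  area0 <- mini_area(hectares = 0)
  expect_message(outz <- compute_rates(mini_use("ALPHA", kg = 5), area0))
  expect_equal(nrow(outz), 0)
  expect_equal(nrow(attr(outz, "undefined")), 1)

  # missing kg is "no data", not zero
  use_na <- mini_use("ALPHA", kg = NA_real_)
  expect_equal(nrow(compute_rates(use_na, area)), 0)
})

test_that("lethal doses per hectare bridge kg to micrograms exactly", {
  expect_equal(lethal_doses_per_ha(0.001, 1), 1e6)
  expect_equal(lethal_doses_per_ha(0, 10), 0)
  expect_equal(lethal_doses_per_ha(0.1, 0.0037), 0.1e9 / 0.0037)
  expect_error(lethal_doses_per_ha(1, 0), "positive")
  expect_error(lethal_doses_per_ha(1, -2), "positive")
})

test_that("toxic load sums insecticide doses and excludes other categories", {
  key <- mini_compound_key()
  area <- mini_area()
  ld50 <- mini_ld50(key$usgs_name, contact = 1, oral = 2)
  rates <- compute_rates(mini_use("ALPHA", kg = 0.1), area) # 0.001 kg/ha
  load <- compute_toxic_load(rates, ld50, key)
  expect_equal(load$lethal_doses_per_ha_contact, 1e6)
  expect_equal(load$lethal_doses_per_ha_oral, 5e5)
  expect_equal(load$insecticide_kg_per_ha, 0.001)

  # additivity across compounds: r * 1e9 * (1/a + 1/b)
  ld2 <- dplyr::bind_rows(
    mini_ld50("ALPHA", contact = 0.5, oral = 1),
    mini_ld50("BETA", contact = 4, oral = 8))
  rates2 <- compute_rates(mini_use(c("ALPHA", "BETA"), kg = 0.2), area)
  load2 <- compute_toxic_load(rates2, ld2, key)
  r <- 0.002
  expect_equal(load2$lethal_doses_per_ha_contact, r * 1e9 * (1 / 0.5 + 1 / 4))
  expect_equal(load2$lethal_doses_per_ha_oral, r * 1e9 * (1 / 1 + 1 / 8))

  # herbicides contribute nothing to the aggregate
  rates3 <- compute_rates(
    mini_use(c("ALPHA", "BETA", "GAMMA", "OMEGA", "ZETA"), kg = 1), area)
  ld3 <- mini_ld50(key$usgs_name, contact = 1, oral = 1)
  load3 <- compute_toxic_load(rates3, ld3, key)
  expect_equal(load3$insecticide_kg_per_ha, 3 * 0.01)

  # an insecticide absent from the LD50 table is a pipeline-order error
  expect_error(compute_toxic_load(rates2, mini_ld50("ALPHA", 1, 1), key),
               "missing from the LD50 table")
})

test_that("aggregate loads truncate after the seed-treatment exclusion year", {
  key <- mini_compound_key()
  area <- mini_area(years = 2012:2017)
  rates <- compute_rates(mini_use("ALPHA", years = 2012:2017, kg = 1), area)
  ld50 <- mini_ld50(key$usgs_name, 1, 1)
  load <- compute_toxic_load(rates, ld50, key)
  expect_equal(sort(unique(load$year)), 2012:2014)
  load_all <- compute_toxic_load(rates, ld50, key, max_year = Inf)
  expect_equal(sort(unique(load_all$year)), 2012:2017)
})

test_that("toxic load is monotone in toxicity and equivariant in scale", {
  set.seed(407)
  key <- mini_compound_key()
  area <- mini_area()
  use <- mini_use(c("ALPHA", "BETA", "GAMMA"), kg = runif(3, 1, 100))
  rates <- compute_rates(use, area)
  ld_a <- mini_ld50(key$usgs_name, contact = 2, oral = 2)
  ld_b <- ld_a
  ld_b$ld50_ug_per_bee[ld_b$compound == "BETA"] <- 1 # more toxic
  la <- compute_toxic_load(rates, ld_a, key)
  lb <- compute_toxic_load(rates, ld_b, key)
  expect_true(all(lb$lethal_doses_per_ha_contact >=
                    la$lethal_doses_per_ha_contact))

  # doubling all kg doubles every rate and load
  use2 <- use
  use2$kg_low <- use$kg_low * 2
  use2$kg_high <- use$kg_high * 2
  rates2 <- compute_rates(use2, area)
  l2 <- compute_toxic_load(rates2, ld_a, key)
  expect_equal(rates2$kg_per_ha, rates$kg_per_ha * 2)
  expect_equal(l2$lethal_doses_per_ha_oral, la$lethal_doses_per_ha_oral * 2)
})

test_that("high-variant rates dominate low-variant rates", {
  set.seed(408)
  area <- mini_area()
  use <- mini_use(c("ALPHA", "BETA"), groups = c("corn", "soybeans"),
                  years = 1997:2000, kg = 1)
  use$kg_low <- runif(nrow(use), 1, 10)
  use$kg_high <- use$kg_low * runif(nrow(use), 1, 1.5)
  low <- compute_rates(use, area, "low")
  high <- compute_rates(use, area, "high")
  expect_true(all(high$kg_per_ha >= low$kg_per_ha))
  expect_equal(unique(low$estimate_variant), "low")
  expect_equal(unique(high$estimate_variant), "high")
})

test_that("load interpolation fills interior gaps per measure", {
  panel <- tibble::tibble(
    state = "PA", usgs_crop_group = "corn", year = c(2005L, 2007L),
    insecticide_kg_per_ha = c(1, 3),
    lethal_doses_per_ha_contact = c(2e6, 4e6),
    lethal_doses_per_ha_oral = c(1e6, 1e6),
    interpolated = FALSE)
  out <- interpolate_loads(panel)
  filled <- out[out$year == 2006, ]
  expect_equal(filled$lethal_doses_per_ha_contact, 3e6)
  expect_equal(filled$insecticide_kg_per_ha, 2)
  expect_equal(filled$lethal_doses_per_ha_oral, 1e6)
  expect_true(filled$interpolated)

  # complete series: identity, nothing marked interpolated
  full <- tibble::tibble(
    state = "PA", usgs_crop_group = "corn", year = 2005:2007,
    insecticide_kg_per_ha = 1:3,
    lethal_doses_per_ha_contact = c(1e6, 2e6, 3e6),
    lethal_doses_per_ha_oral = c(2e6, 3e6, 4e6),
    interpolated = FALSE)
  out2 <- interpolate_loads(full)
  expect_equal(out2$insecticide_kg_per_ha, as.numeric(1:3))
  expect_false(any(out2$interpolated))

  # two separate gaps fill from their own nearest brackets
  two_gaps <- tibble::tibble(
    state = "PA", usgs_crop_group = "corn",
    year = c(2000L, 2002L, 2004L, 2006L)[-2],
    insecticide_kg_per_ha = c(0, 4, 6),
    lethal_doses_per_ha_contact = c(0, 4e6, 6e6),
    lethal_doses_per_ha_oral = c(0, 4e6, 6e6),
    interpolated = FALSE)
  out3 <- interpolate_loads(two_gaps)
  # gap 2001-2003 brackets (2000, 2004); gap 2005 brackets (2004, 2006)
  expect_equal(out3$insecticide_kg_per_ha[out3$year == 2002], 2)
  expect_equal(out3$insecticide_kg_per_ha[out3$year == 2005], 5)
  expect_true(all(out3$interpolated[out3$year %in% c(2001, 2002, 2003, 2005)]))
})

test_that("the pipeline recovers planted ground truth end to end", {
  cfg <- sim_config(seed = 51, n_states = 2,
                    groups = c("corn", "soybeans", "wheat"),
                    n_compounds = c(insecticide = 4, fungicide = 2,
                                    herbicide = 2),
                    years = 1997:2002, missing_rate_use = 0,
                    unresolved_insecticides = 2)
  dir <- withr::local_tempdir()
  b <- generate_fixture_bundle(cfg, dir)
  res <- suppressMessages(run_pipeline(dir))
  truth <- b$truth$rates[!is.na(b$truth$rates$rate_low), ]
  m <- dplyr::inner_join(res$rates, truth,
                         by = c("compound", "state", "usgs_crop_group",
                                "year"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$kg_per_ha, m$rate_low, tolerance = 1e-9)
  ml <- dplyr::inner_join(res$loads, b$truth$loads,
                          by = c("state", "usgs_crop_group", "year"))
  expect_equal(nrow(ml), nrow(b$truth$loads))
  expect_equal(ml$lethal_doses_per_ha_contact.x,
               ml$lethal_doses_per_ha_contact.y, tolerance = 1e-9)
  expect_equal(ml$lethal_doses_per_ha_oral.x,
               ml$lethal_doses_per_ha_oral.y, tolerance = 1e-9)
})
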
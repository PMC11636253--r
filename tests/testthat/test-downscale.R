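test_that("unit shares follow 2020 generation, with the uniform fallback", {
  fleet <- tibble::tibble(
    unit_id = c("A", "B", "C", "D", "E"),
    cluster_id = c("K1", "K1", "K2", "K3", "K3"),
    gen_2020_mwh = c(60, 40, 100, 0, 0),
    status = "existing"
  )
  shares <- unit_generation_shares(fleet)
  s <- stats::setNames(shares$share, shares$unit_id)
  expect_equal(s[["A"]], 0.6)
  expect_equal(s[["B"]], 0.4)
  expect_equal(s[["C"]], 1.0) # single-unit cluster
  expect_equal(s[["D"]], 0.5) # zero-generation cluster: uniform
  expect_equal(s[["E"]], 0.5)
  sums <- shares |> dplyr::summarise(s = sum(share), .by = cluster_id)
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("grow-in-place fills planned, then retired, then existing sites", {
  fleet <- tibble::tibble(
    unit_id = c("P1", "R1", "E1"),
    county_id = c("c1", "c2", "c3"),
    region_id = 1L,
    fuel = "gas",
    capacity_mw = c(60, 80, 100),
    status = c("planned", "retired_site", "existing")
  )
  out <- grow_in_place_allocate(
    tibble::tibble(region_id = 1L, fuel = "gas", mw = 100), fleet
  )
  a <- stats::setNames(out$added_mw, out$site_id)
  expect_equal(a[["P1"]], 60)
  expect_equal(a[["R1"]], 40)
  expect_equal(sum(out$added_mw), 100)
})

test_that("grow-in-place three-tier overflow matches the hand-applied rule", {
  fleet <- tibble::tibble(
    unit_id = c("P1", "R1", "R2", "E1", "E2"),
    county_id = paste0("c", 1:5),
    region_id = 1L,
    fuel = "gas",
    capacity_mw = c(60, 50, 150, 100, 300),
    status = c("planned", "retired_site", "retired_site", "existing", "existing")
  )
  out <- grow_in_place_allocate(
    tibble::tibble(region_id = 1L, fuel = "gas", mw = 300), fleet
  )
  a <- stats::setNames(out$added_mw, out$site_id)
  # planned capped at 60; retired tier absorbs its 200 MW of capacity
  # proportionally; the remaining 40 MW goes to existing units 1:3.
  expect_equal(a[["P1"]], 60)
  expect_equal(a[["R1"]], 50)
  expect_equal(a[["R2"]], 150)
  expect_equal(a[["E1"]], 10)
  expect_equal(a[["E2"]], 30)
  expect_equal(sum(out$added_mw), 300)
})

test_that("grow-in-place handles zero requests and impossible regions", {
  fleet <- tibble::tibble(
    unit_id = "E1", county_id = "c1", region_id = 1L, fuel = "gas",
    capacity_mw = 10, status = "existing"
  )
  expect_equal(
    nrow(grow_in_place_allocate(
      tibble::tibble(region_id = 1L, fuel = "gas", mw = 0), fleet
    )),
    0L
  )
  expect_error(
    grow_in_place_allocate(
      tibble::tibble(region_id = 2L, fuel = "gas", mw = 5), fleet
    ),
    regexp = "Region 2",
    class = "aqequity_structural_error"
  )
})

test_that("EGU county emissions split by shares and aggregate by county", {
  cty <- two_county_geo()
  fleet <- tibble::tibble(
    unit_id = c("A", "B"), plant_id = c("A", "B"), cluster_id = "K1",
    county_id = c("A", "B"), fuel = "gas",
    capacity_mw = 1, gen_2020_mwh = c(60, 40),
    status = "existing", height_bin = "medium"
  )
  shares <- unit_generation_shares(fleet)
  regional <- tibble::tibble(
    region_id = 1L, sector = "egu", technology = "gas",
    pollutant = "so2", period = 2020L, tons = 100
  )
  out <- egu_emissions_to_counties(regional, shares, fleet, cty)
  expect_equal(out$tons[out$county_id == "A"], 60)
  expect_equal(out$tons[out$county_id == "B"], 40)
  # both units in the same county: county receives the full total
  fleet2 <- dplyr::mutate(fleet, county_id = "A")
  out2 <- egu_emissions_to_counties(regional, unit_generation_shares(fleet2), fleet2, cty)
  expect_equal(out2$tons, 100)
})

test_that("randomized fleet conserves regional totals through EGU downscaling", {
  cty <- gen_counties(3, 4, 500, seed = 31)
  fleet <- gen_egu_fleet(cty, 7, 3, seed = 31)
  shares <- unit_generation_shares(fleet)
  cfg <- emissions_config()
  sched <- policy_schedule("current_policy")
  stock <- fleet_turnover(sched, init_vehicle_stock(c(light_duty = 1e5)), 3)
  pop <- gen_population(cty, demographic_trajectory(), 1e6, seed = 31)
  surrogate <- gen_vmt_surrogate(cty, pop, seed = 31)
  regional <- gen_regional_emissions(sched, stock, fleet, surrogate, cty, cfg)
  out <- egu_emissions_to_counties(regional, shares, fleet, cty)
  # brute-force re-summation oracle
  by_region <- out |>
    dplyr::left_join(dplyr::select(cty, county_id, region_id), by = "county_id") |>
    dplyr::summarise(tons = sum(tons), .by = c(region_id, pollutant, period))
  expected <- regional |>
    dplyr::filter(sector == "egu") |>
    dplyr::summarise(tons = sum(tons), .by = c(region_id, pollutant, period))
  cmp <- dplyr::inner_join(by_region, expected,
    by = c("region_id", "pollutant", "period"), suffix = c("_ds", "_reg")
  )
  expect_equal(nrow(cmp), nrow(expected))
  expect_true(all(abs(cmp$tons_ds - cmp$tons_reg) <=
    1e-9 * pmax(cmp$tons_reg, 1e-300)))
})

test_that("VMT downscaling reproduces surrogate shares and conserves mass", {
  cty <- tibble::tibble(
    county_id = c("a", "b", "c"), region_id = 1L,
    cx = 0, cy = 0, area = 1, pw_x = 0, pw_y = 0
  )
  surrogate <- structure(list(
    vmt = tidyr::expand_grid(
      county_id = c("a", "b", "c"),
      vehicle_type = "light_duty",
      surrogate_year = c(2023L, 2026L, 2032L)
    ) |>
      dplyr::mutate(vmt = rep(c(10, 30, 60), each = 3)),
    national_scale = tidyr::expand_grid(
      vehicle_type = "light_duty", period = seq(2035L, 2050L, 5L)
    ) |> dplyr::mutate(factor = 1.1)
  ), class = "aq_vmt_surrogate")
  regional <- tibble::tibble(region_id = 1L, vehicle_type = "light_duty", vmt = 500)
  out <- downscale_vmt(regional, surrogate, cty, 2030)
  expect_equal(sort(out$vmt), c(50, 150, 300))
  expect_equal(sum(out$vmt), 500)
  # a uniform national factor cancels in the shares
  out2040 <- downscale_vmt(regional, surrogate, cty, 2040)
  expect_equal(
    dplyr::arrange(out2040, county_id)$vmt,
    dplyr::arrange(out, county_id)$vmt,
    tolerance = 1e-12
  )
  # zero surrogate with positive VMT errors
  surrogate0 <- surrogate
  surrogate0$vmt$vmt <- 0
  expect_error(downscale_vmt(regional, surrogate0, cty, 2030),
    class = "aqequity_structural_error"
  )
})

test_that("VMT to emissions multiplies factors and grounds the release", {
  vmt <- tibble::tibble(
    county_id = c("a", "a"), technology = c("ice", "zev"),
    period = 2020L, vmt = c(1e6, 5e6)
  )
  ef <- tibble::tibble(
    technology = c("ice", "zev"), pollutant = "nox",
    tons_per_mile = c(1e-5, 0)
  )
  out <- vmt_to_emissions(vmt, ef)
  expect_equal(out$tons, 10) # zev contributes nothing
  expect_equal(out$height_bin, "ground")
  # two-technology county total is the sum of per-technology products
  ef2 <- dplyr::mutate(ef, tons_per_mile = c(1e-5, 2e-6))
  out2 <- vmt_to_emissions(vmt, ef2)
  expect_equal(out2$tons, 1e6 * 1e-5 + 5e6 * 2e-6)
  # a technology with no factors errors
  expect_error(
    vmt_to_emissions(dplyr::mutate(vmt, technology = "hover"), ef),
    class = "aqequity_structural_error"
  )
})

test_that("downscaling is homogeneous: scaling regional totals scales county values", {
  cty <- gen_counties(2, 3, 400, seed = 13)
  fleet <- gen_egu_fleet(cty, 4, 2, seed = 13)
  shares <- unit_generation_shares(fleet)
  regional <- tibble::tibble(
    region_id = c(1L, 2L), sector = "egu", technology = "gas",
    pollutant = "nox", period = 2020L, tons = c(100, 250)
  )
  out1 <- egu_emissions_to_counties(regional, shares, fleet, cty)
  out3 <- egu_emissions_to_counties(
    dplyr::mutate(regional, tons = tons * 3), shares, fleet, cty
  )
  cmp <- dplyr::inner_join(out1, out3,
    by = c("county_id", "pollutant", "height_bin", "period"),
    suffix = c("_1", "_3")
  )
  expect_equal(cmp$tons_3, 3 * cmp$tons_1, tolerance = 1e-12)
})
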
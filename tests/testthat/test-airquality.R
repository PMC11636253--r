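test_that("sigma_z follows its closed form and scaling properties", {
  expect_equal(sigma_z(1000), 37.94733192202055, tolerance = 1e-12)
  # limit towards zero distance
  expect_lt(sigma_z(1e-6), 1e-4)
  # linear in the leading coefficient
  x <- c(100, 1000, 50000)
  expect_equal(
    sigma_z(x, c(a = 0.12, b = 0.0015, c = 0.5)),
    2 * sigma_z(x, c(a = 0.06, b = 0.0015, c = 0.5)),
    tolerance = 1e-12
  )
  # monotone nondecreasing under the default rural coefficients
  xs <- seq(10, 5e5, length.out = 400)
  expect_true(all(diff(sigma_z(xs)) >= 0))
  expect_error(sigma_z(0), class = "aqequity_invalid_argument")
  expect_error(sigma_z(-5), class = "aqequity_invalid_argument")
})

test_that("plume kernel matches hand-evaluated closed-form values", {
  met <- met_config()
  # values evaluated independently from the closed form
  expect_equal(plume_kernel(10000, 0, "ground", met, 1),
    0.00011438047860779642,
    tolerance = 1e-12
  )
  expect_equal(plume_kernel(300000, 0, "ground", met, 1),
    3.5891076293617725e-06,
    tolerance = 1e-12
  )
  expect_equal(plume_kernel(5000, 0, "medium", met, 1),
    2.316985846378989e-06,
    tolerance = 1e-12
  )
  # zero emission rate, zero concentration
  expect_equal(plume_kernel(10000, 0, "ground", met, 0), 0)
  # linear in the emission rate
  expect_equal(
    plume_kernel(25000, 0, "ground", met, 7),
    7 * plume_kernel(25000, 0, "ground", met, 1),
    tolerance = 1e-12
  )
})

test_that("ground-source kernels decay monotonically with distance", {
  met <- met_config()
  xs <- seq(500, 8e5, length.out = 500)
  vals <- plume_kernel(xs, 0, "ground", met, 1)
  expect_true(all(diff(vals) < 0))
  expect_true(all(is.finite(vals)) && all(vals >= 0))
})

test_that("elevated sources are attenuated at near-field receptors", {
  met <- met_config()
  for (x in c(1000, 2000, 3000)) {
    expect_lt(
      plume_kernel(x, 0, "medium", met, 1),
      plume_kernel(x, 0, "ground", met, 1)
    )
  }
})

test_that("inorganic partitioning follows the ammonia budget rules", {
  # ammonia-rich: full neutralization
  p <- partition_inorganic(1, 3, 4)
  expect_equal(p$sulfate_pm, 132)
  expect_equal(p$nitrate_pm, 2 * 80) # free ammonia 2 limits nitrate
  # no ammonia: acidic sulfate, no nitrate
  p0 <- partition_inorganic(1, 3, 0)
  expect_equal(p0$sulfate_pm, 98)
  expect_equal(p0$nitrate_pm, 0)
  # abundant ammonia: nitrate demand fully met
  p2 <- partition_inorganic(1, 3, 100)
  expect_equal(p2$nitrate_pm, 3 * 80)
  expect_error(partition_inorganic(-1, 0, 0), class = "aqequity_invalid_argument")
})

test_that("primary PM2.5 marginals equal the kernel row for any baseline", {
  cty <- gen_counties(2, 3, 300, seed = 17)
  met <- met_config()
  chem <- chem_config()
  baseline <- tibble::tibble(
    county_id = cty$county_id, pollutant = "so2",
    height_bin = "medium", tons = 500
  )
  k <- kernel_matrix(cty, "ground", met)
  src <- cty$county_id[2]
  m <- marginal_concentrations(src, "pm25", "ground", baseline, cty, met, chem)
  expect_equal(unname(m), unname(k[src, ]), tolerance = 1e-12)
  # and for a different baseline
  baseline2 <- dplyr::mutate(baseline, tons = 5000)
  m2 <- marginal_concentrations(src, "pm25", "ground", baseline2, cty, met, chem)
  expect_equal(m, m2, tolerance = 1e-12)
})

test_that("NOx marginals vanish at receptors with no free ammonia", {
  cty <- gen_counties(1, 2, 200, seed = 19)
  met <- met_config()
  chem <- chem_config(ammonia_umol = 0)
  baseline <- tibble::tibble(
    county_id = cty$county_id[1], pollutant = "pm25",
    height_bin = "ground", tons = 100
  )
  m <- marginal_concentrations(cty$county_id[1], "nox", "ground", baseline, cty, met, chem)
  expect_true(all(m == 0))
})

test_that("SO2 marginals equal an independent two-run field difference", {
  cty <- gen_counties(2, 3, 300, seed = 23)
  met <- met_config()
  chem <- chem_config()
  baseline <- tidyr::expand_grid(
    county_id = cty$county_id,
    pollutant = aq_pollutants()
  ) |>
    dplyr::mutate(
      height_bin = ifelse(pollutant == "so2", "medium", "ground"),
      tons = 200 + 50 * seq_along(county_id)
    )
  src <- cty$county_id[4]
  m <- marginal_concentrations(src, "so2", "medium", baseline, cty, met, chem)
  # oracle: brute-force two-field difference with an independent implementation
  f0 <- oracle_field_total(baseline, cty)
  pert <- dplyr::bind_rows(
    baseline,
    tibble::tibble(county_id = src, pollutant = "so2", height_bin = "medium", tons = 1)
  )
  f1 <- oracle_field_total(pert, cty)
  expect_equal(unname(m), f1 - f0, tolerance = 1e-9)
})

test_that("zero-ton perturbations return the zero marginal vector", {
  cty <- tiny_counties()
  baseline <- tibble::tibble(
    county_id = cty$county_id[1], pollutant = "so2",
    height_bin = "medium", tons = 10
  )
  m <- marginal_concentrations(cty$county_id[1], "so2", "medium", baseline, cty,
    add_tons = 0
  )
  expect_true(all(m == 0))
})

test_that("total field is linear and zero for zero emissions", {
  cty <- tiny_counties()
  baseline <- tibble::tibble(
    county_id = cty$county_id, pollutant = "so2",
    height_bin = "medium", tons = 100
  )
  sr <- build_sr_set(cty, baseline)
  emissions <- tidyr::expand_grid(
    county_id = cty$county_id, pollutant = aq_pollutants()
  ) |>
    dplyr::mutate(
      sector = "egu",
      height_bin = ifelse(pollutant == "pm25", "ground", "medium"),
      period = 2020L,
      tons = 10 * seq_along(county_id)
    )
  f1 <- total_pm_field(emissions, sr)
  f2 <- total_pm_field(dplyr::mutate(emissions, tons = 2 * tons), sr)
  expect_equal(f2$conc, 2 * f1$conc, tolerance = 1e-12)
  f0 <- total_pm_field(dplyr::mutate(emissions, tons = 0), sr)
  expect_true(all(f0$conc == 0))
  expect_true(all(is.finite(f1$conc)) && all(f1$conc >= 0))
})

test_that("missing SR entries and unknown pollutants raise structured errors", {
  cty <- tiny_counties()
  baseline <- tibble::tibble(
    county_id = cty$county_id[1], pollutant = "so2",
    height_bin = "medium", tons = 10
  )
  sr <- build_sr_set(cty, baseline, height_bins = "ground")
  emissions <- tibble::tibble(
    county_id = cty$county_id[1], sector = "egu", pollutant = "so2",
    height_bin = "tall", period = 2020L, tons = 5
  )
  expect_error(total_pm_field(emissions, sr), regexp = "so2.tall")
  expect_error(
    marginal_concentrations(cty$county_id[1], "o3", "ground", baseline, cty),
    class = "aqequity_invalid_argument"
  )
})
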
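test_that("the log-risk coefficient follows its closed form", {
  expect_equal(beta_from_rr(1, 10), 0)
  expect_equal(beta_from_rr(1.06, 10), 0.005826890812397583, tolerance = 1e-12)
  expect_equal(beta_from_rr(exp(0.1), 10), 0.01, tolerance = 1e-12)
  expect_error(beta_from_rr(0), class = "aqequity_invalid_argument")
  expect_error(beta_from_rr(1.06, 0), class = "aqequity_invalid_argument")
})

test_that("delta mortality matches its closed form and limits", {
  beta <- beta_from_rr(1.06, 10)
  expect_equal(delta_mortality(0, 0.01, beta, 1e5), 0)
  expect_equal(delta_mortality(1, 0.01, beta, 1e5),
    5.809947409221472,
    tolerance = 1e-12
  )
  # small-signal limit: dMort ~ y0 pop beta dPM
  dpm <- 1e-6 / beta
  lin <- 0.01 * 1e5 * beta * dpm
  expect_equal(delta_mortality(dpm, 0.01, beta, 1e5) / lin, 1, tolerance = 1e-5)
  # 1% linearity whenever beta * dPM <= 0.02
  dpm2 <- 0.02 / beta
  lin2 <- 0.01 * 1e5 * beta * dpm2
  expect_lt(abs(delta_mortality(dpm2, 0.01, beta, 1e5) - lin2) / lin2, 0.01)
  # concave, increasing, bounded by y0 * pop
  x <- seq(0, 500, length.out = 100)
  y <- delta_mortality(x, 0.01, beta, 1e5)
  expect_true(all(diff(y) > 0))
  expect_true(all(diff(diff(y)) < 1e-9))
  expect_true(all(y <= 0.01 * 1e5))
  expect_error(delta_mortality(1, 1.5, beta, 10), class = "aqequity_invalid_argument")
})

# A small field/population pair shared by the variant tests.
health_fixture <- function() {
  ids <- c("c1", "c2")
  field <- tibble::tibble(
    county_id = rep(ids, 2), period = rep(c(2020L, 2025L), each = 2),
    sector = "egu", conc = c(2, 1, 1, 0.5)
  )
  pop <- tidyr::expand_grid(
    county_id = ids, group = aq_groups(), age_band = aq_age_bands(),
    period = c(2020L, 2025L)
  ) |>
    dplyr::mutate(persons = 1000 + 100 * seq_along(county_id))
  list(field = field, pop = pop)
}

test_that("zero fields give zero deaths under every variant", {
  fx <- health_fixture()
  field0 <- dplyr::mutate(fx$field, conc = 0)
  deaths <- scenario_deaths(field0, fx$pop)
  expect_true(all(deaths$deaths == 0))
  expect_setequal(unique(deaths$variant), c("A", "B", "C"))
})

test_that("variants A and B coincide when rates do not vary by race", {
  fx <- health_fixture()
  flat <- tidyr::expand_grid(group = aq_groups(), age_band = aq_adult_bands()) |>
    dplyr::mutate(rate = dplyr::case_match(
      age_band, "30-64" ~ 0.004, "65-79" ~ 0.02, "80+" ~ 0.12
    ))
  dA <- scenario_deaths(fx$field, fx$pop, rates = flat, variants = "A")
  dB <- scenario_deaths(fx$field, fx$pop, rates = flat, variants = "B")
  cmp <- dplyr::inner_join(dA, dB, by = c("county_id", "group", "period"),
    suffix = c("_a", "_b")
  )
  expect_equal(cmp$deaths_a, cmp$deaths_b, tolerance = 1e-12)
})

test_that("raising a group's relative risk raises only that group's deaths", {
  fx <- health_fixture()
  base <- scenario_deaths(fx$field, fx$pop, variants = "B") |>
    dplyr::summarise(deaths = sum(deaths), .by = group)
  rc <- scenario_deaths(fx$field, fx$pop, variants = "C") |>
    dplyr::summarise(deaths = sum(deaths), .by = group)
  # Black non-Hispanic beta multiplier is 3: strictly more deaths than B
  expect_gt(
    rc$deaths[rc$group == "black_nh"],
    base$deaths[base$group == "black_nh"]
  )
  # deaths increase monotonically in the multiplier
  d1 <- scenario_deaths(fx$field, fx$pop, variants = "C",
    beta_multipliers = c(black_nh = 2, white_nh = 1, hispanic = 1, other = 1)
  )
  d2 <- scenario_deaths(fx$field, fx$pop, variants = "C",
    beta_multipliers = c(black_nh = 4, white_nh = 1, hispanic = 1, other = 1)
  )
  expect_gt(
    sum(d2$deaths[d2$group == "black_nh"]),
    sum(d1$deaths[d1$group == "black_nh"])
  )
  expect_error(scenario_deaths(fx$field, fx$pop, variants = "D"),
    class = "aqequity_configuration_error"
  )
})

test_that("deaths add exactly over counties and age bands", {
  fx <- health_fixture()
  beta <- beta_from_rr(1.06, 10)
  rates <- default_mortality_rates()
  deaths <- scenario_deaths(fx$field, fx$pop, rates = rates, variants = "B")
  # recompute one group/period cell by explicit summation
  g <- "hispanic"
  t <- 2020L
  manual <- 0
  for (cid in c("c1", "c2")) {
    conc <- fx$field$conc[fx$field$county_id == cid & fx$field$period == t]
    for (ab in aq_adult_bands()) {
      y0 <- rates$rate[rates$group == g & rates$age_band == ab]
      pp <- fx$pop$persons[fx$pop$county_id == cid & fx$pop$group == g &
        fx$pop$age_band == ab & fx$pop$period == t]
      manual <- manual + y0 * pp * (1 - exp(-beta * conc))
    }
  }
  got <- deaths |>
    dplyr::filter(group == g, period == t) |>
    dplyr::summarise(d = sum(deaths)) |>
    dplyr::pull(d)
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("avoided deaths weight periods by the years they represent", {
  ids <- "c1"
  mk <- function(annual) {
    out <- tidyr::expand_grid(
      variant = c("A", "B", "C"), county_id = ids,
      group = "white_nh", period = aq_periods()
    ) |>
      dplyr::mutate(deaths = annual)
    class(out) <- c("aq_health_result", class(out))
    out
  }
  pol <- mk(5)
  base <- mk(15)
  av <- avoided_deaths(pol, base)
  # 10 deaths/yr avoided over 31 years
  expect_equal(av$avoided, rep(10 * 31, 3))
  expect_equal(unname(avoided_range(av)), c(310, 310))
  # identical scenarios avoid nothing
  av0 <- avoided_deaths(pol, pol)
  expect_equal(av0$avoided, rep(0, 3))
  # min-max over variants
  av$avoided <- c(100, 150, 120)
  expect_equal(unname(avoided_range(av)), c(100, 150))
  # mismatched universes error
  expect_error(avoided_deaths(dplyr::filter(pol, period != 2050), base),
    class = "aqequity_structural_error"
  )
})

test_that("per-capita deaths divide by the all-ages group population", {
  fx <- health_fixture()
  deaths <- tibble::tibble(
    variant = "B", county_id = "c1", group = c("white_nh", "black_nh"),
    period = 2020L, deaths = c(50, 50)
  )
  class(deaths) <- c("aq_health_result", class(deaths))
  pop <- tibble::tibble(
    county_id = "c1", group = c("white_nh", "black_nh"), age_band = "0-29",
    period = 2020L, persons = c(1e6, 5e5)
  )
  pc <- per_capita_deaths(deaths, pop, 2020)
  expect_equal(pc$per_100k[pc$group == "white_nh"], 5.0)
  # equal deaths, half the population: double the rate
  expect_equal(pc$per_100k[pc$group == "black_nh"], 10.0)
  pop0 <- dplyr::mutate(pop, persons = 0)
  expect_error(per_capita_deaths(deaths, pop0, 2020),
    class = "aqequity_invalid_argument"
  )
})
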
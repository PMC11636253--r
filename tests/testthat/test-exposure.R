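make_field <- function(county_ids, conc, period = 2020L) {
  tibble::tibble(
    county_id = county_ids, period = period, sector = "egu", conc = conc
  )
}

make_pop <- function(county_ids, by_group, period = 2020L) {
  # by_group: named list group -> vector of county populations
  purrr::imap_dfr(by_group, function(p, g) {
    tibble::tibble(
      county_id = county_ids, group = g, age_band = "30-64",
      period = period, persons = p
    )
  })
}

test_that("uniform fields give every group the same exposure", {
  ids <- c("a", "b", "c")
  field <- make_field(ids, c(2, 2, 2))
  pop <- make_pop(ids, list(black_nh = c(1, 5, 10), white_nh = c(10, 5, 1)))
  expect_equal(pw_exposure(field, pop, "black_nh", 2020), 2)
  expect_equal(pw_exposure(field, pop, "white_nh", 2020), 2)
  expect_equal(exposure_disparity(field, pop, "black_nh", 2020), 0)
})

test_that("worked two-county example reproduces exposures and disparity", {
  ids <- c("c1", "c2")
  field <- make_field(ids, c(2, 1))
  pop <- make_pop(ids, list(g1 = c(10, 0), g2 = c(0, 10)))
  expect_equal(pw_exposure(field, pop, "g1", 2020), 2.0)
  expect_equal(pw_exposure(field, pop, "total", 2020), 1.5)
  expect_equal(exposure_disparity(field, pop, "g1", 2020), 0.5)
  expect_error(
    pw_exposure(field, make_pop(ids, list(g1 = c(0, 0))), "g1", 2020),
    class = "aqequity_undefined_exposure"
  )
})

test_that("population-weighted disparities sum to zero on random instances", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      ids <- sprintf("c%02d", 1:20)
      field <- make_field(ids, runif(20, 0, 5))
      pop <- make_pop(ids, list(
        black_nh = runif(20, 0, 1e4), white_nh = runif(20, 0, 5e4),
        hispanic = runif(20, 0, 2e4), other = runif(20, 0, 1e4)
      ))
    })
    groups <- aq_groups()
    d <- vapply(groups, function(g) exposure_disparity(field, pop, g, 2020), 1)
    p <- vapply(groups, function(g) {
      sum(pop$persons[pop$group == g])
    }, 1)
    expect_lt(abs(sum(p * d)) / sum(p * abs(d) + 1e-300), 1e-9)
    # translation leaves disparities unchanged, shifts exposures
    field2 <- dplyr::mutate(field, conc = conc + 3)
    for (g in groups) {
      expect_equal(
        exposure_disparity(field2, pop, g, 2020),
        exposure_disparity(field, pop, g, 2020),
        tolerance = 1e-9
      )
      expect_equal(
        pw_exposure(field2, pop, g, 2020),
        pw_exposure(field, pop, g, 2020) + 3,
        tolerance = 1e-9
      )
    }
  }
})

test_that("pw_exposure matches an independent weighted mean on a random instance", {
  withr::with_seed(99, {
    ids <- sprintf("c%02d", 1:20)
    conc <- runif(20, 0, 10)
    w <- runif(20, 0, 1e4)
  })
  field <- make_field(ids, conc)
  pop <- make_pop(ids, list(g = w))
  expect_equal(pw_exposure(field, pop, "g", 2020), sum(conc * w) / sum(w),
    tolerance = 1e-12
  )
})

test_that("weighted quantiles match stated examples", {
  expect_equal(weighted_quantile(c(1, 2, 3), c(1, 1, 1), 0.5), 2)
  expect_equal(weighted_quantile(5, 2, c(0, 0.3, 1)), c(5, 5, 5))
  expect_equal(weighted_quantile(c(1, 2, 3, 4), c(1, 1, 1, 7), 0.5), 4)
  expect_error(weighted_quantile(1:3, c(0, 0, 0), 0.5),
    class = "aqequity_invalid_argument"
  )
  expect_error(weighted_quantile(1:3, c(1, 1), 0.5),
    class = "aqequity_invalid_argument"
  )
})

test_that("weighted quantiles agree with the enumeration oracle", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(1:12, 1)
      v <- round(runif(n, 0, 10), 2)
      w <- runif(n, 0.1, 5)
      for (q in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
        expect_equal(
          weighted_quantile(v, w, q),
          oracle_weighted_quantile(v, w, q)
        )
      }
    }
  })
})

test_that("midpoint convention interpolates and stays within range", {
  v <- c(1, 2, 3)
  w <- c(1, 1, 1)
  expect_equal(weighted_quantile(v, w, 0.5, type = "midpoint"), 2)
  expect_equal(weighted_quantile(v, w, 0, type = "midpoint"), 1)
  expect_equal(weighted_quantile(v, w, 1, type = "midpoint"), 3)
  q25 <- weighted_quantile(v, w, 0.25, type = "midpoint")
  expect_true(q25 > 1 && q25 < 2)
})

test_that("exposure summaries order their quantiles", {
  withr::with_seed(5, {
    ids <- sprintf("c%02d", 1:15)
    field <- make_field(ids, runif(15, 0, 4))
    pop <- make_pop(ids, list(
      black_nh = runif(15, 0, 1e4), white_nh = runif(15, 0, 1e4),
      hispanic = runif(15, 0, 1e4), other = runif(15, 0, 1e4)
    ))
  })
  summ <- exposure_summary(field, pop)
  qs <- summ |>
    dplyr::filter(startsWith(metric, "q")) |>
    tidyr::pivot_wider(names_from = metric, values_from = value)
  expect_true(all(qs$q10 <= qs$q25 & qs$q25 <= qs$q50 &
    qs$q50 <= qs$q75 & qs$q75 <= qs$q90))
  # pw exposure lies within the value range
  pw <- summ |> dplyr::filter(metric == "pw_exposure")
  expect_true(all(pw$value >= min(field$conc) & pw$value <= max(field$conc)))
})
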
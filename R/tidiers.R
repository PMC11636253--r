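# broom-style tidiers for the pipeline's result objects.

#' Tidy a scenario run
#'
#' One row per county, group, period and variant with the expected deaths,
#' joined with the county's PM2.5-equivalent concentration.
#'
#' @param x An `aq_scenario_run`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.aq_scenario_run <- function(x, ...) {
  conc <- x$field |>
    summarise(conc = sum(.data$conc), .by = c("county_id", "period"))
  as_tibble(x$deaths) |>
    left_join(conc, by = c("county_id", "period")) |>
    mutate(scenario = x$scenario, .before = 1)
}

#' One-row summary of a scenario run
#'
#' @param x An `aq_scenario_run`.
#' @param ... Unused.
#' @return A one-row tibble: scenario, 2020 and 2050 total population-weighted
#'   exposure, and cumulative deaths under each variant.
#' @exportS3Method generics::glance
glance.aq_scenario_run <- function(x, ...) {
  expo <- as_tibble(x$exposure) |>
    filter(.data$group == "total", .data$metric == "pw_exposure")
  cum <- cumulative_deaths(x$deaths) |>
    tidyr::pivot_wider(
      names_from = "variant", values_from = "cumulative",
      names_prefix = "cumulative_deaths_"
    )
  bind_cols(
    tibble(
      scenario = x$scenario,
      pw_exposure_2020 = expo$value[expo$period == 2020],
      pw_exposure_2050 = expo$value[expo$period == 2050]
    ),
    cum
  )
}

#' Tidy a scenario comparison
#'
#' The long exposure/disparity table across scenarios, groups and periods.
#'
#' @param x An `aq_comparison`.
#' @param ... Unused.
#' @return A tibble `scenario, period, group, metric, value`.
#' @exportS3Method generics::tidy
tidy.aq_comparison <- function(x, ...) {
  as_tibble(x$exposure)
}

#' One-row-per-scenario summary of a comparison
#'
#' @param x An `aq_comparison`.
#' @param ... Unused.
#' @return A tibble with the avoided-deaths range per scenario.
#' @exportS3Method generics::glance
glance.aq_comparison <- function(x, ...) {
  x$avoided |>
    summarise(
      avoided_min = min(.data$avoided), avoided_max = max(.data$avoided),
      .by = "scenario"
    )
}
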
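# Concentration-response mortality model: log-linear hazard form, three
# relative-risk / baseline-mortality variants, cumulative and avoided deaths
# against the current-policy baseline, and per-capita rates.

#' Default baseline mortality rates
#'
#' Synthetic annual all-cause baseline mortality rates (deaths per
#' person-year) by race-ethnicity and age band, shaped like recent U.S.
#' vital-statistics data: strongly increasing in age, slightly elevated for
#' Black non-Hispanic adults, and lower for Hispanic adults (the "Hispanic
#' paradox"). Only ages 30+ enter the concentration-response function.
#'
#' @return Tibble `group, age_band, rate` of class `aq_mortality_rates`.
#' @export
default_mortality_rates <- function() {
  out <- tribble(
    ~group, ~age_band, ~rate,
    "black_nh", "30-64", 0.0050, "black_nh", "65-79", 0.030, "black_nh", "80+", 0.14,
    "white_nh", "30-64", 0.0040, "white_nh", "65-79", 0.025, "white_nh", "80+", 0.13,
    "hispanic", "30-64", 0.0030, "hispanic", "65-79", 0.020, "hispanic", "80+", 0.11,
    "other", "30-64", 0.0032, "other", "65-79", 0.021, "other", "80+", 0.11
  )
  class(out) <- c("aq_mortality_rates", class(out))
  out
}

# Race-collapsed (all-person) rates: population-weighted across groups using
# the 2020 population, per age band.
all_person_rates <- function(rates, pop) {
  weights <- pop |>
    filter(.data$period == 2020) |>
    summarise(persons = sum(.data$persons), .by = c("group", "age_band"))
  collapsed <- rates |>
    inner_join(weights, by = c("group", "age_band")) |>
    summarise(
      rate = sum(.data$rate * .data$persons) / sum(.data$persons),
      .by = "age_band"
    )
  tidyr::expand_grid(group = unique(rates$group), collapsed) |>
    select("group", "age_band", "rate")
}

#' Relative-risk configuration
#'
#' The three estimate variants:
#'
#' * `"A"` — constant relative risk, all-person (race-collapsed) baseline
#'   mortality rates.
#' * `"B"` — constant relative risk, race- and age-specific rates.
#' * `"C"` — race-specific relative risk, race- and age-specific rates.
#'
#' The constant relative risk defaults to 1.06 per 10 ug/m^3 (a Krewski-style
#' cohort estimate); race-specific risks are expressed as multipliers on the
#' log-risk coefficient beta (Di-style), with the Black non-Hispanic
#' multiplier of 3 chosen so that race-specific risk produces roughly a
#' 3-fold increase in that group's per-capita deaths. Both are placeholders
#' standing in for literature values, exposed here as configuration.
#'
#' @param variant `"A"`, `"B"` or `"C"`.
#' @param rr_constant Relative risk per `delta_c` ug/m^3.
#' @param delta_c Concentration change the relative risk is quoted for
#'   (ug/m^3).
#' @param beta_multipliers Named per-group multipliers on beta (variant C).
#' @return Object of class `aq_rr_config` with per-group `beta` (per
#'   ug/m^3).
#' @export
rr_config <- function(variant = c("B", "A", "C"),
                      rr_constant = 1.06,
                      delta_c = 10,
                      beta_multipliers = c(
                        black_nh = 3, white_nh = 0.9,
                        hispanic = 1.2, other = 1.1
                      )) {
  variant <- match.arg(variant)
  if (rr_constant <= 0) abort_invalid("`rr_constant` must be > 0.")
  beta0 <- beta_from_rr(rr_constant, delta_c)
  beta <- if (variant == "C") {
    beta_multipliers[aq_groups()] * beta0
  } else {
    stats::setNames(rep(beta0, length(aq_groups())), aq_groups())
  }
  structure(
    list(
      variant = variant, rr_constant = rr_constant, delta_c = delta_c,
      beta = beta
    ),
    class = "aq_rr_config"
  )
}

#' Log-risk coefficient from a relative risk
#'
#' `beta = log(rr) / delta_c`, the per-ug/m^3 log-hazard slope implied by a
#' relative risk quoted for a `delta_c` ug/m^3 change.
#'
#' @param rr Relative risk (> 0).
#' @param delta_c Concentration change the risk is quoted for (> 0).
#' @return beta, per ug/m^3.
#' @export
beta_from_rr <- function(rr, delta_c = 10) {
  if (any(rr <= 0)) abort_invalid("`rr` must be > 0.")
  if (any(delta_c <= 0)) abort_invalid("`delta_c` must be > 0.")
  log(rr) / delta_c
}

#' Expected premature deaths from a concentration change
#'
#' The hazard-based concentration-response form
#' `dMort = y0 * pop * (1 - exp(-beta * dPM))`: continuous, increasing and
#' concave in the concentration change, bounded by `y0 * pop`, and linear
#' (`y0 * pop * beta * dPM`) in the small-signal limit. This is the single
#' place the functional form lives, so an alternative parameterization is a
#' one-line change.
#'
#' @param delta_pm Concentration change, ug/m^3.
#' @param y0 Baseline mortality rate, deaths per person-year (in `[0, 1]`).
#' @param beta Log-risk coefficient, per ug/m^3.
#' @param pop Exposed population, persons (>= 0).
#' @return Expected deaths per year (vectorized).
#' @export
delta_mortality <- function(delta_pm, y0, beta, pop) {
  if (any(pop < 0)) abort_invalid("`pop` must be >= 0.")
  if (any(y0 < 0 | y0 > 1)) abort_invalid("`y0` must lie in [0, 1].")
  y0 * pop * (1 - exp(-beta * delta_pm))
}

#' Deaths by county, group and period for one or more variants
#'
#' Applies the concentration-response function to the policy-attributable
#' concentration field, the adult (30+) population, and the variant's
#' baseline-mortality and relative-risk choices, independently for each
#' requested variant.
#'
#' @param field Concentration field tibble (`county_id, period, conc`;
#'   sector attributions are summed).
#' @param pop Population table.
#' @param rates Baseline mortality rates (race- and age-specific); variant A
#'   collapses them to all-person rates internally.
#' @param variants Character subset of `c("A", "B", "C")`.
#' @param rr_constant,delta_c,beta_multipliers Passed to [rr_config()].
#' @return Tibble `variant, county_id, group, period, deaths` of class
#'   `aq_health_result`.
#' @export
scenario_deaths <- function(field, pop, rates = default_mortality_rates(),
                            variants = c("A", "B", "C"),
                            rr_constant = 1.06, delta_c = 10,
                            beta_multipliers = c(
                              black_nh = 3, white_nh = 0.9,
                              hispanic = 1.2, other = 1.1
                            )) {
  bad <- setdiff(variants, c("A", "B", "C"))
  if (length(bad)) {
    abort(sprintf("Unknown variant(s): %s.", paste(bad, collapse = ", ")),
      class = c("aqequity_configuration_error", "aqequity_error")
    )
  }
  conc <- field |>
    summarise(conc = sum(.data$conc), .by = c("county_id", "period"))
  adults <- pop |> filter(.data$age_band %in% aq_adult_bands())

  out <- purrr::map_dfr(variants, function(v) {
    vrates <- if (v == "A") all_person_rates(rates, pop) else rates
    rrc <- rr_config(v,
      rr_constant = rr_constant, delta_c = delta_c,
      beta_multipliers = beta_multipliers
    )
    adults |>
      inner_join(vrates, by = c("group", "age_band")) |>
      inner_join(conc, by = c("county_id", "period")) |>
      mutate(deaths = delta_mortality(.data$conc, .data$rate,
        rrc$beta[.data$group], .data$persons
      )) |>
      summarise(deaths = sum(.data$deaths),
        .by = c("county_id", "group", "period")
      ) |>
      mutate(variant = v)
  }) |>
    select("variant", "county_id", "group", "period", "deaths")
  class(out) <- c("aq_health_result", class(out))
  out
}

# Annual deaths -> cumulative deaths over the horizon, per variant:
# each period's annual result stands for five calendar years (one for 2050).
cumulative_deaths <- function(result) {
  w <- period_year_weights()
  result |>
    summarise(
      cumulative = sum(.data$deaths * w[as.character(.data$period)]),
      .by = "variant"
    )
}

#' Cumulative avoided deaths relative to a baseline scenario
#'
#' Per variant, cumulative deaths are the sum over periods of annual deaths
#' times the calendar years each period represents (five for 2020-2045, one
#' for 2050: a 31-year horizon); avoided deaths are baseline minus policy.
#' The reported range is the minimum and maximum across variants.
#'
#' @param policy,baseline `aq_health_result` tables on the same
#'   county/group/period universe.
#' @return Tibble `variant, policy, baseline, avoided` plus attributes; use
#'   [avoided_range()] for the (min, max) pair.
#' @export
avoided_deaths <- function(policy, baseline) {
  key_p <- policy |> distinct(.data$variant, .data$period)
  key_b <- baseline |> distinct(.data$variant, .data$period)
  if (!identical(arrange_all_df(key_p), arrange_all_df(key_b))) {
    abort_structural("`policy` and `baseline` cover different variant/period universes.")
  }
  cp <- cumulative_deaths(policy) |> rename(policy = "cumulative")
  cb <- cumulative_deaths(baseline) |> rename(baseline = "cumulative")
  inner_join(cp, cb, by = "variant") |>
    mutate(avoided = .data$baseline - .data$policy)
}

arrange_all_df <- function(df) df[do.call(order, as.list(df)), , drop = FALSE]

#' Min-max range of cumulative avoided deaths across variants
#' @param avoided Output of [avoided_deaths()].
#' @return Named numeric `c(min, max)`.
#' @export
avoided_range <- function(avoided) {
  c(min = min(avoided$avoided), max = max(avoided$avoided))
}

#' Per-capita deaths by group
#'
#' Group deaths per 100,000 persons, dividing by the group's all-ages
#' population (whole-population rates).
#'
#' @param result `aq_health_result` table.
#' @param pop Population table.
#' @param period Modelled period.
#' @return Tibble `variant, group, deaths, persons, per_100k`.
#' @export
per_capita_deaths <- function(result, pop, period) {
  d <- result |>
    filter(.data$period == .env$period) |>
    summarise(deaths = sum(.data$deaths), .by = c("variant", "group"))
  p <- pop |>
    filter(.data$period == .env$period) |>
    summarise(persons = sum(.data$persons), .by = "group")
  if (any(p$persons <= 0)) {
    abort_invalid("Every group must have positive population.")
  }
  d |>
    inner_join(p, by = "group") |>
    mutate(per_100k = .data$deaths / .data$persons * 1e5)
}
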
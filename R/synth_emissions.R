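# Stylized regional emission trajectories: the stand-in for a full energy
# system optimization run. Power-sector emissions scale the 2020 fossil fleet
# by a scenario-specific factor; on-road emissions follow ICE vehicle miles
# times fleet-average emission factors.

#' Emission-system configuration
#'
#' Emission factors and scenario response parameters. Defaults are set at
#' realistic national-average magnitudes:
#'
#' * EGU factors (short tons per MWh): coal roughly an order of magnitude
#'   dirtier than gas for SO2; `other` (non-fossil) emits nothing. New fossil
#'   capacity built for electrified transport demand uses gas factors.
#' * On-road ICE factors (short tons per mile) with medium/heavy-duty NOx
#'   roughly ten times light-duty.
#' * `cp_decline_rate` — continuous annual decline of power fossil emissions
#'   under current policy (existing incentives and retirements), 3%/yr.
#' * `tax_elasticity` / `tax_floor` — power fossil emissions scale as
#'   `max(floor, exp(-elasticity * tax))`; with the default tax path the floor
#'   binds in the last modelled periods, producing a late-horizon plateau.
#' * `tax_transport_elasticity` — the (much weaker) on-road response to the
#'   carbon price.
#' * `ef_improvement_rate` — fleet-average ICE emission-factor improvement
#'   from tightening vehicle standards, 2%/yr, applied in every scenario.
#' * `mwh_per_zev` — annual electricity demand per zero-emission vehicle; in
#'   ICE-ban scenarios this demand increment is served partly by fossil
#'   generation (in proportion to the scenario's remaining fossil share),
#'   the mechanism by which a vehicle ban can raise power-sector emissions
#'   absent a clean electricity standard.
#'
#' @param egu_ef Tibble `fuel, pollutant, tons_per_mwh`.
#' @param onroad_ef Tibble `technology, pollutant, tons_per_mile`.
#' @param cp_decline_rate,tax_elasticity,tax_floor,tax_transport_elasticity,ef_improvement_rate
#'   Scalars, see above.
#' @param mwh_per_zev Named vector, MWh per vehicle-year by vehicle class.
#' @param fossil_capacity_factor Capacity factor used to convert incremental
#'   generation to capacity when siting new fossil units.
#' @return Object of class `aq_emissions_config`.
#' @export
emissions_config <- function(
    egu_ef = tribble(
      ~fuel, ~pollutant, ~tons_per_mwh,
      "coal", "nox", 8e-4, "coal", "so2", 1.2e-3, "coal", "pm25", 1e-4,
      "gas", "nox", 4e-4, "gas", "so2", 1e-5, "gas", "pm25", 3e-5,
      "other", "nox", 0, "other", "so2", 0, "other", "pm25", 0
    ),
    onroad_ef = tribble(
      ~technology, ~pollutant, ~tons_per_mile,
      "light_duty_ice", "nox", 2.2e-7, "light_duty_ice", "so2", 5e-9,
      "light_duty_ice", "pm25", 1e-8,
      "medium_heavy_duty_ice", "nox", 2.0e-6, "medium_heavy_duty_ice", "so2", 2e-8,
      "medium_heavy_duty_ice", "pm25", 6e-8
    ),
    cp_decline_rate = 0.03,
    tax_elasticity = 0.03,
    tax_floor = 0.15,
    tax_transport_elasticity = 0.004,
    ef_improvement_rate = 0.02,
    mwh_per_zev = c(light_duty = 4, medium_heavy_duty = 15),
    fossil_capacity_factor = 0.5) {
  if (any(egu_ef$tons_per_mwh < 0) || any(onroad_ef$tons_per_mile < 0)) {
    abort_invalid("Emission factors must be nonnegative.")
  }
  structure(
    list(
      egu_ef = egu_ef, onroad_ef = onroad_ef,
      cp_decline_rate = cp_decline_rate,
      tax_elasticity = tax_elasticity, tax_floor = tax_floor,
      tax_transport_elasticity = tax_transport_elasticity,
      ef_improvement_rate = ef_improvement_rate,
      mwh_per_zev = mwh_per_zev,
      fossil_capacity_factor = fossil_capacity_factor
    ),
    class = "aq_emissions_config"
  )
}

# Scenario scaling of 2020 power-sector fossil emissions.
egu_scale_factor <- function(schedule, periods, cfg) {
  cp <- exp(-cfg$cp_decline_rate * (periods - 2020))
  switch(schedule$name,
    current_policy = cp,
    ice_ban = cp,
    ces = ,
    ice_ban_ces = {
      cf <- schedule$ces_clean_fraction$fraction[match(periods, schedule$ces_clean_fraction$period)]
      ifelse(periods < 2030, cp, 1 - cf)
    },
    carbon_tax = {
      tax <- schedule$carbon_tax$usd_per_t[match(periods, schedule$carbon_tax$period)]
      ifelse(tax <= 0, 1, pmax(cfg$tax_floor, exp(-cfg$tax_elasticity * tax)))
    },
    net_zero = schedule$netzero_cap_fraction$fraction[
      match(periods, schedule$netzero_cap_fraction$period)
    ],
    abort_invalid(sprintf("Unknown scenario '%s'.", schedule$name))
  )
}

# Scenario scaling applied on top of the ICE-stock-driven on-road emissions.
onroad_scale_factor <- function(schedule, periods, cfg) {
  switch(schedule$name,
    carbon_tax = {
      tax <- schedule$carbon_tax$usd_per_t[match(periods, schedule$carbon_tax$period)]
      exp(-cfg$tax_transport_elasticity * tax)
    },
    net_zero = schedule$netzero_cap_fraction$fraction[
      match(periods, schedule$netzero_cap_fraction$period)
    ],
    rep(1, length(periods))
  )
}

# Regional VMT by vehicle type and period from the county surrogate:
# surrogate-year mapping (2020->2023, 2025->2026, 2030->2032) and national
# scaling factors relative to 2032 for later periods.
regional_vmt_by_period <- function(surrogate, counties, periods = aq_periods()) {
  vmt <- surrogate$vmt |>
    left_join(select(counties, "county_id", "region_id"), by = "county_id")
  purrr::map_dfr(periods, function(t) {
    yr <- period_surrogate_year(t)
    base <- vmt |>
      filter(.data$surrogate_year == yr) |>
      summarise(vmt = sum(.data$vmt), .by = c("region_id", "vehicle_type"))
    if (t >= 2035) {
      sc <- surrogate$national_scale |> filter(.data$period == t)
      base <- base |>
        left_join(select(sc, "vehicle_type", "factor"), by = "vehicle_type") |>
        mutate(vmt = .data$vmt * .data$factor) |>
        select(-"factor")
    }
    mutate(base, period = t)
  })
}

period_surrogate_year <- function(period) {
  if (period < 2025) 2023L else if (period < 2030) 2026L else 2032L
}

#' Generate regional emission trajectories for a policy scenario
#'
#' The energy-system stand-in. Power-sector emissions start from the 2020
#' fleet (unit generation times fuel emission factors, summed by region and
#' fuel) and scale by a scenario factor: the current-policy decline, one minus
#' the clean-electricity fraction, an exponential carbon-tax response with a
#' floor, or the linear net-zero cap. ICE-ban scenarios add an
#' electrified-transport demand increment served by new gas capacity in
#' proportion to the scenario's remaining fossil share (technology
#' `"gas_new"`). On-road emissions are regional ICE vehicle-miles (surrogate
#' totals times the surviving ICE stock share from [fleet_turnover()]) times
#' fleet-average emission factors, with a secular emission-factor improvement
#' and, for the carbon tax and net-zero scenarios, an additional demand
#' response.
#'
#' @param schedule [policy_schedule()] for the scenario.
#' @param stock Vehicle stock per period from [fleet_turnover()].
#' @param egu_fleet EGU fleet from [gen_egu_fleet()].
#' @param surrogate VMT surrogate from [gen_vmt_surrogate()].
#' @param counties County tibble (for region membership).
#' @param cfg An [emissions_config()].
#'
#' @return Tibble `region_id, sector, technology, pollutant, period, tons`
#'   (short tons per year). EGU technologies are the fuels plus `"gas_new"`
#'   for the electrification increment; on-road technologies are
#'   `<class>_ice`.
#' @export
gen_regional_emissions <- function(schedule, stock, egu_fleet, surrogate,
                                   counties, cfg = emissions_config()) {
  if (!inherits(schedule, "aq_policy_schedule")) {
    abort_invalid("`schedule` must be a policy_schedule().")
  }
  periods <- aq_periods()

  # --- power sector: 2020 regional fossil emissions scaled per scenario ----
  base_egu <- egu_fleet |>
    filter(.data$status == "existing") |>
    left_join(select(counties, "county_id", "region_id"), by = "county_id") |>
    inner_join(cfg$egu_ef, by = "fuel", relationship = "many-to-many") |>
    summarise(
      tons_2020 = sum(.data$gen_2020_mwh * .data$tons_per_mwh),
      .by = c("region_id", "fuel", "pollutant")
    )

  scale_t <- tibble(period = periods, scale = egu_scale_factor(schedule, periods, cfg))
  egu <- base_egu |>
    tidyr::expand_grid(period = periods) |>
    left_join(scale_t, by = "period") |>
    mutate(
      sector = "egu",
      technology = .data$fuel,
      tons = .data$tons_2020 * .data$scale
    ) |>
    select("region_id", "sector", "technology", "pollutant", "period", "tons")

  # --- electrification increment (ICE-ban scenarios only) ------------------
  increment <- NULL
  if (schedule$name %in% c("ice_ban", "ice_ban_ces")) {
    gen_2020_total <- sum(egu_fleet$gen_2020_mwh[egu_fleet$status == "existing"])
    fossil_share_2020 <- sum(egu_fleet$gen_2020_mwh[
      egu_fleet$status == "existing" & egu_fleet$fuel %in% c("coal", "gas")
    ]) / gen_2020_total
    region_share <- egu_fleet |>
      filter(.data$status == "existing") |>
      left_join(select(counties, "county_id", "region_id"), by = "county_id") |>
      summarise(gen = sum(.data$gen_2020_mwh), .by = "region_id") |>
      mutate(share = .data$gen / sum(.data$gen))

    zev_count <- stock |>
      filter(.data$technology == "zev") |>
      summarise(count = sum(.data$count), .by = c("vehicle_class", "period")) |>
      mutate(extra_mwh = .data$count * cfg$mwh_per_zev[.data$vehicle_class]) |>
      summarise(extra_mwh = sum(.data$extra_mwh), .by = "period")

    gas_ef <- cfg$egu_ef |> filter(.data$fuel == "gas")
    increment <- zev_count |>
      left_join(scale_t, by = "period") |>
      mutate(fossil_mwh = .data$extra_mwh * fossil_share_2020 * .data$scale) |>
      tidyr::expand_grid(region_share |> select("region_id", "share")) |>
      tidyr::expand_grid(gas_ef |> select("pollutant", "tons_per_mwh")) |>
      mutate(
        sector = "egu",
        technology = "gas_new",
        tons = .data$fossil_mwh * .data$share * .data$tons_per_mwh
      ) |>
      select("region_id", "sector", "technology", "pollutant", "period", "tons")
  }

  # --- on-road: ICE vehicle-miles times fleet-average factors --------------
  rvmt <- regional_vmt_by_period(surrogate, counties, periods)
  ice <- ice_stock_share(stock)
  onroad_t <- tibble(
    period = periods,
    policy_scale = onroad_scale_factor(schedule, periods, cfg),
    ef_improve = exp(-cfg$ef_improvement_rate * (periods - 2020))
  )
  onroad <- rvmt |>
    left_join(select(ice, "vehicle_class", "period", "ice_share"),
      by = c(vehicle_type = "vehicle_class", "period")
    ) |>
    # vehicle types absent from the stock table have no combustion fleet
    mutate(ice_share = tidyr::replace_na(.data$ice_share, 0)) |>
    mutate(technology = paste0(.data$vehicle_type, "_ice")) |>
    inner_join(cfg$onroad_ef, by = "technology", relationship = "many-to-many") |>
    left_join(onroad_t, by = "period") |>
    mutate(
      sector = "onroad",
      tons = .data$vmt * .data$ice_share * .data$tons_per_mile *
        .data$ef_improve * .data$policy_scale
    ) |>
    select("region_id", "sector", "technology", "pollutant", "period", "tons")

  out <- bind_rows(egu, increment, onroad) |>
    arrange(.data$period, .data$region_id, .data$sector, .data$technology, .data$pollutant)
  stopifnot(all(out$tons >= 0))
  out
}
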
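# Synthetic electricity-generating-unit fleet and county VMT surrogate.

#' Generate a synthetic EGU fleet
#'
#' Builds `n_clusters` clusters of generating units (the dispatch-model
#' aggregation level), each confined to one region, with 2020 generation drawn
#' log-normally around a typical capacity factor. Every region additionally
#' receives at least one planned unit and one retired-site record — the
#' candidate locations for the grow-in-place siting heuristic. Existing fossil
#' units are assigned the medium effective-height bin (250-500 m), where the
#' bulk of power-sector emissions are discharged; planned and retired records
#' carry zero 2020 generation.
#'
#' Cluster fuels cycle gas / coal / other within each region, so every region
#' has at least one gas cluster and (with three or more clusters) a coal
#' cluster.
#'
#' @param counties County tibble from [gen_counties()].
#' @param n_clusters Total number of clusters (assigned to regions round-robin).
#' @param units_per_cluster Units per cluster.
#' @param seed Integer seed.
#'
#' @return Tibble `unit_id, plant_id, cluster_id, county_id, fuel,
#'   capacity_mw, gen_2020_mwh, status, height_bin`. Planned and retired-site
#'   rows have `cluster_id = NA`.
#' @export
gen_egu_fleet <- function(counties, n_clusters, units_per_cluster, seed) {
  check_scalar_number(n_clusters, "n_clusters", positive = TRUE, integerish = TRUE)
  check_scalar_number(units_per_cluster, "units_per_cluster",
    positive = TRUE, integerish = TRUE
  )
  check_scalar_number(seed, "seed", integerish = TRUE)
  check_columns(counties, c("county_id", "region_id"), "counties")

  n_regions <- max(counties$region_id)
  fuel_cycle <- c("gas", "coal", "other")

  clusters <- tibble(
    cluster_id = sprintf("K%03d", seq_len(n_clusters)),
    region_id = ((seq_len(n_clusters) - 1L) %% n_regions) + 1L
  ) |>
    mutate(
      rank_in_region = dplyr::row_number(),
      fuel = fuel_cycle[((.data$rank_in_region - 1L) %% 3L) + 1L],
      .by = "region_id"
    )

  withr::with_seed(seed, {
    units <- clusters |>
      tidyr::expand_grid(unit_slot = seq_len(as.integer(units_per_cluster))) |>
      mutate(
        unit_id = sprintf("U%04d", dplyr::row_number()),
        plant_id = sprintf("P%04d", dplyr::row_number()),
        capacity_mw = rlnorm(dplyr::n(), meanlog = log(300), sdlog = 0.6),
        gen_2020_mwh = pmin(
          .data$capacity_mw * 8760 * 0.45 * rlnorm(dplyr::n(), 0, 0.4),
          .data$capacity_mw * 8760 * 0.9
        ),
        status = "existing",
        height_bin = "medium"
      )
    units$county_id <- purrr::map_chr(units$region_id, function(r) {
      pool <- counties$county_id[counties$region_id == r]
      pool[sample.int(length(pool), 1L)]
    })

    # Candidate sites for new capacity: one planned (gas) and one retired
    # (coal or gas) record per region, at seeded county locations.
    sites <- tidyr::expand_grid(
      region_id = seq_len(n_regions),
      status = c("planned", "retired_site")
    ) |>
      mutate(
        unit_id = sprintf("S%04d", dplyr::row_number()),
        plant_id = .data$unit_id,
        cluster_id = NA_character_,
        fuel = ifelse(.data$status == "planned", "gas",
          sample(c("coal", "gas"), dplyr::n(), replace = TRUE)
        ),
        capacity_mw = rlnorm(dplyr::n(), meanlog = log(400), sdlog = 0.5),
        gen_2020_mwh = 0,
        height_bin = "medium"
      )
    sites$county_id <- purrr::map_chr(sites$region_id, function(r) {
      pool <- counties$county_id[counties$region_id == r]
      pool[sample.int(length(pool), 1L)]
    })
  })

  cols <- c(
    "unit_id", "plant_id", "cluster_id", "county_id", "fuel",
    "capacity_mw", "gen_2020_mwh", "status", "height_bin"
  )
  bind_rows(select(units, all_of(cols)), select(sites, all_of(cols)))
}

#' Generate a synthetic county VMT surrogate
#'
#' County vehicle-miles-traveled by vehicle type for the three surrogate years
#' (2023, 2026, 2032), proportional to county population times a seeded
#' urban/rural multiplier, plus national scaling factors (relative to 2032) by
#' vehicle type for the 2035-2050 periods. The national factors follow gentle
#' deterministic growth (about 0.8%/yr from 2032) with small multiplicative
#' noise, the shape national VMT projections typically take.
#'
#' @param counties County tibble.
#' @param population Population table from [gen_population()] (must cover 2020).
#' @param seed Integer seed.
#' @param miles_per_capita Named vector of annual per-capita VMT by vehicle
#'   type.
#'
#' @return List of class `aq_vmt_surrogate` with elements `vmt` (tibble
#'   `county_id, vehicle_type, surrogate_year, vmt`) and `national_scale`
#'   (tibble `vehicle_type, period, factor`).
#' @export
gen_vmt_surrogate <- function(counties, population, seed,
                              miles_per_capita = c(light_duty = 9000, medium_heavy_duty = 900)) {
  check_scalar_number(seed, "seed", integerish = TRUE)
  check_columns(counties, "county_id", "counties")
  check_columns(population, c("county_id", "period", "persons"), "population")
  if (!2020 %in% population$period) {
    abort_invalid("`population` must cover the 2020 period.")
  }

  pop2020 <- population |>
    filter(.data$period == 2020) |>
    summarise(persons = sum(.data$persons), .by = "county_id")

  year_factor <- c(`2023` = 1, `2026` = 1.025, `2032` = 1.075)
  types <- names(miles_per_capita)
  late_periods <- aq_periods()[aq_periods() >= 2035]

  withr::with_seed(seed, {
    mult <- exp(runif(nrow(pop2020), -0.3, 0.3))
    noise <- matrix(exp(runif(length(types) * length(late_periods), -0.01, 0.01)),
      nrow = length(types)
    )
  })

  vmt <- tidyr::expand_grid(
    county_id = pop2020$county_id,
    vehicle_type = types,
    surrogate_year = c(2023L, 2026L, 2032L)
  ) |>
    left_join(mutate(pop2020, mult = mult), by = "county_id") |>
    mutate(
      vmt = .data$persons * .data$mult *
        miles_per_capita[.data$vehicle_type] *
        year_factor[as.character(.data$surrogate_year)]
    ) |>
    select("county_id", "vehicle_type", "surrogate_year", "vmt")

  national_scale <- tidyr::expand_grid(
    vehicle_type = types,
    period = late_periods
  ) |>
    mutate(
      factor = 1.008^(.data$period - 2032) *
        as.vector(noise[cbind(
          match(.data$vehicle_type, types),
          match(.data$period, late_periods)
        )])
    )

  structure(
    list(vmt = vmt, national_scale = national_scale),
    class = "aq_vmt_surrogate"
  )
}
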
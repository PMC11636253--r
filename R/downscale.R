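# Downscaling: regional emission totals to counties. The power sector uses
# constant 2020 unit generation shares within each cluster plus a
# grow-in-place heuristic for new capacity; the transport sector uses VMT
# spatial surrogates. Both paths conserve mass exactly.

#' Unit generation shares within clusters
#'
#' The percent of a cluster's generation attributable to each unit, computed
#' from 2020 generation and held constant over time. Clusters whose recorded
#' 2020 generation is zero get uniform shares across their units, preserving
#' mass conservation.
#'
#' @param fleet EGU fleet tibble (only `status == "existing"` rows are used;
#'   every cluster must have at least one existing unit).
#' @return Tibble `cluster_id, unit_id, share`; shares sum to one per cluster.
#' @export
unit_generation_shares <- function(fleet) {
  check_columns(fleet, c("unit_id", "cluster_id", "gen_2020_mwh", "status"), "fleet")
  existing <- fleet |>
    filter(.data$status == "existing", !is.na(.data$cluster_id))
  if (nrow(existing) == 0L) {
    abort_structural("Fleet contains no existing units in clusters.")
  }
  existing |>
    mutate(
      total = sum(.data$gen_2020_mwh),
      share = ifelse(.data$total > 0,
        .data$gen_2020_mwh / .data$total,
        1 / dplyr::n()
      ),
      .by = "cluster_id"
    ) |>
    select("cluster_id", "unit_id", "share")
}

#' Grow-in-place allocation of new capacity
#'
#' Sites new capacity within each region and fuel in three tiers: first to
#' planned sites (proportional to planned capacity, capped at that capacity),
#' overflow to retired-site locations (likewise capped), and any remainder to
#' existing same-fuel units proportional to their capacity (uncapped). The
#' allocated total equals the requested total exactly.
#'
#' @param new_capacity Tibble `region_id, fuel, mw` of capacity to site.
#' @param fleet EGU fleet tibble with `status` in existing / planned /
#'   retired_site.
#' @return Tibble `site_id, county_id, region_id, fuel, added_mw` (zero-MW
#'   requests produce no rows).
#' @export
grow_in_place_allocate <- function(new_capacity, fleet) {
  check_columns(new_capacity, c("region_id", "fuel", "mw"), "new_capacity")
  check_columns(fleet, c("unit_id", "county_id", "fuel", "capacity_mw", "status"), "fleet")
  if (any(new_capacity$mw < 0)) abort_invalid("`new_capacity$mw` must be >= 0.")

  fleet_r <- fleet
  if (!"region_id" %in% names(fleet_r)) {
    abort_structural("`fleet` must carry a `region_id` column (join counties first).")
  }

  alloc_one <- function(region_id, fuel, mw) {
    if (mw == 0) return(NULL)
    pool <- fleet_r |>
      filter(.data$region_id == .env$region_id, .data$fuel == .env$fuel)
    tiers <- list(
      planned = filter(pool, .data$status == "planned"),
      retired = filter(pool, .data$status == "retired_site"),
      existing = filter(pool, .data$status == "existing")
    )
    if (sum(purrr::map_int(tiers, nrow)) == 0L) {
      abort_structural(sprintf(
        "Region %s has new %s capacity but no candidate site of any tier.",
        region_id, fuel
      ))
    }
    remaining <- mw
    out <- list()
    for (tier in c("planned", "retired")) {
      sites <- tiers[[tier]]
      if (remaining <= 0 || nrow(sites) == 0L) next
      cap <- sum(sites$capacity_mw)
      take <- min(remaining, cap)
      if (take > 0 && cap > 0) {
        out[[tier]] <- sites |>
          transmute(
            site_id = .data$unit_id, .data$county_id, .data$region_id,
            .data$fuel, added_mw = take * .data$capacity_mw / cap
          )
        remaining <- remaining - take
      }
    }
    if (remaining > 1e-12) {
      sites <- tiers$existing
      if (nrow(sites) == 0L || sum(sites$capacity_mw) <= 0) {
        abort_structural(sprintf(
          "Region %s: %0.1f MW of %s capacity cannot be sited (no existing capacity).",
          region_id, remaining, fuel
        ))
      }
      out$existing <- sites |>
        transmute(
          site_id = .data$unit_id, .data$county_id, .data$region_id,
          .data$fuel, added_mw = remaining * .data$capacity_mw / sum(sites$capacity_mw)
        )
    }
    bind_rows(out)
  }

  purrr::pmap_dfr(
    new_capacity |> select("region_id", "fuel", "mw"),
    function(region_id, fuel, mw) alloc_one(region_id, fuel, mw)
  )
}

#' Downscale regional power-sector emissions to counties
#'
#' Regional emissions for each fuel are split across that region's clusters in
#' proportion to cluster 2020 generation, then across units by their constant
#' generation shares, and summed by county. Emissions carried by the
#' `"gas_new"` technology (the electrification increment) are split across
#' grow-in-place `additions` in proportion to added capacity, each addition
#' acting as a one-unit cluster. County sums reproduce the regional totals
#' exactly.
#'
#' @param regional Regional emissions tibble (sector `"egu"` rows) from
#'   [gen_regional_emissions()].
#' @param shares Unit shares from [unit_generation_shares()].
#' @param fleet EGU fleet tibble.
#' @param counties County tibble (region membership).
#' @param additions Optional grow-in-place additions from
#'   [grow_in_place_allocate()]; required if `regional` contains `"gas_new"`
#'   emissions.
#' @return Tibble `county_id, sector, pollutant, height_bin, period, tons`.
#' @export
egu_emissions_to_counties <- function(regional, shares, fleet, counties,
                                      additions = NULL) {
  egu <- regional |> filter(.data$sector == "egu")
  if (nrow(egu) == 0L) {
    return(tibble(
      county_id = character(), sector = character(), pollutant = character(),
      height_bin = character(), period = integer(), tons = double()
    ))
  }

  units <- fleet |>
    filter(.data$status == "existing") |>
    left_join(select(counties, "county_id", "region_id"), by = "county_id") |>
    inner_join(shares, by = c("cluster_id", "unit_id"))
  if (anyNA(units$share)) {
    abort_structural("Share table is missing entries for some fleet units.")
  }
  cluster_weight <- units |>
    summarise(gen = sum(.data$gen_2020_mwh),
      .by = c("region_id", "fuel", "cluster_id")
    ) |>
    mutate(
      cweight = ifelse(sum(.data$gen) > 0, .data$gen / sum(.data$gen),
        1 / dplyr::n()
      ),
      .by = c("region_id", "fuel")
    )

  fuel_rows <- egu |> filter(.data$technology != "gas_new")
  missing <- fuel_rows |>
    filter(.data$tons > 0) |>
    distinct(.data$region_id, .data$technology) |>
    anti_join(cluster_weight,
      by = c("region_id", technology = "fuel")
    )
  if (nrow(missing)) {
    abort_structural(sprintf(
      "No clusters for region x fuel: %s.",
      paste(sprintf("%s/%s", missing$region_id, missing$technology), collapse = ", ")
    ))
  }

  unit_alloc <- units |>
    inner_join(cluster_weight |> select("cluster_id", "cweight"), by = "cluster_id")
  by_unit <- fuel_rows |>
    inner_join(unit_alloc,
      by = c("region_id", technology = "fuel"),
      relationship = "many-to-many"
    ) |>
    mutate(tons = .data$tons * .data$cweight * .data$share) |>
    summarise(tons = sum(.data$tons),
      .by = c("county_id", "pollutant", "height_bin", "period")
    )

  new_rows <- egu |> filter(.data$technology == "gas_new", .data$tons > 0)
  by_new <- NULL
  if (nrow(new_rows)) {
    if (is.null(additions) || nrow(additions) == 0L) {
      abort_structural("Regional emissions include 'gas_new' but no `additions` were given.")
    }
    add_w <- additions |>
      mutate(aweight = .data$added_mw / sum(.data$added_mw), .by = "region_id")
    by_new <- new_rows |>
      inner_join(add_w, by = "region_id", relationship = "many-to-many") |>
      mutate(tons = .data$tons * .data$aweight, height_bin = "medium") |>
      summarise(tons = sum(.data$tons),
        .by = c("county_id", "pollutant", "height_bin", "period")
      )
  }

  bind_rows(by_unit, by_new) |>
    summarise(tons = sum(.data$tons),
      .by = c("county_id", "pollutant", "height_bin", "period")
    ) |>
    mutate(sector = "egu") |>
    select("county_id", "sector", "pollutant", "height_bin", "period", "tons") |>
    arrange(.data$period, .data$county_id, .data$pollutant)
}

#' Downscale regional VMT to counties via the spatial surrogate
#'
#' County VMT is the regional total times the county's share of the (scaled)
#' surrogate within its region: periods 2020-2034 map to the 2023 / 2026 /
#' 2032 surrogate years; periods from 2035 apply the national per-type scaling
#' factors to the 2032 surrogate (a uniform factor cancels in the
#' within-region shares). County VMT sums to the regional totals exactly.
#'
#' @param regional_vmt Tibble `region_id, vehicle_type, vmt` for one period.
#' @param surrogate [gen_vmt_surrogate()] output.
#' @param counties County tibble.
#' @param period The modelled period the VMT belongs to.
#' @return Tibble `county_id, vehicle_type, period, vmt`.
#' @export
downscale_vmt <- function(regional_vmt, surrogate, counties, period) {
  check_columns(regional_vmt, c("region_id", "vehicle_type", "vmt"), "regional_vmt")
  yr <- period_surrogate_year(period)
  s <- surrogate$vmt |>
    filter(.data$surrogate_year == yr) |>
    left_join(select(counties, "county_id", "region_id"), by = "county_id")
  if (period >= 2035) {
    sc <- surrogate$national_scale |> filter(.data$period == .env$period)
    s <- s |>
      left_join(select(sc, "vehicle_type", "factor"), by = "vehicle_type") |>
      mutate(vmt = .data$vmt * .data$factor) |>
      select(-"factor")
  }
  shares <- s |>
    mutate(share = .data$vmt / sum(.data$vmt),
      ssum = sum(.data$vmt),
      .by = c("region_id", "vehicle_type")
    )

  joined <- regional_vmt |>
    inner_join(shares |> select("county_id", "region_id", "vehicle_type", "share", "ssum"),
      by = c("region_id", "vehicle_type"), relationship = "many-to-many"
    )
  bad <- regional_vmt |>
    filter(.data$vmt > 0) |>
    anti_join(
      shares |> filter(.data$ssum > 0) |> distinct(.data$region_id, .data$vehicle_type),
      by = c("region_id", "vehicle_type")
    )
  if (nrow(bad)) {
    abort_structural(sprintf(
      "Zero surrogate total for region(s) with positive VMT: %s.",
      paste(unique(bad$region_id), collapse = ", ")
    ))
  }
  joined |>
    transmute(
      .data$county_id, .data$vehicle_type, period = as.integer(.env$period),
      vmt = .data$vmt * .data$share
    )
}

#' Convert county VMT to county emissions
#'
#' Multiplies county vehicle-miles by per-mile emission factors for each
#' technology and sums to county x pollutant. Transport emissions are released
#' at ground level.
#'
#' @param county_vmt Tibble `county_id, technology, period, vmt`.
#' @param emission_factor Tibble `technology, pollutant, tons_per_mile`
#'   (zero-emission technologies may simply be absent only if their VMT is
#'   absent too; every technology present in `county_vmt` must have factors).
#' @return Tibble `county_id, sector, pollutant, height_bin, period, tons`.
#' @export
vmt_to_emissions <- function(county_vmt, emission_factor) {
  check_columns(county_vmt, c("county_id", "technology", "period", "vmt"), "county_vmt")
  check_columns(emission_factor, c("technology", "pollutant", "tons_per_mile"),
    "emission_factor"
  )
  if (any(emission_factor$tons_per_mile < 0)) {
    abort_invalid("Emission factors must be >= 0.")
  }
  missing <- setdiff(unique(county_vmt$technology), unique(emission_factor$technology))
  if (length(missing)) {
    abort_structural(sprintf(
      "No emission factors for technology: %s.", paste(missing, collapse = ", ")
    ))
  }
  county_vmt |>
    inner_join(emission_factor, by = "technology", relationship = "many-to-many") |>
    mutate(tons = .data$vmt * .data$tons_per_mile) |>
    summarise(tons = sum(.data$tons), .by = c("county_id", "pollutant", "period")) |>
    mutate(sector = "onroad", height_bin = "ground") |>
    select("county_id", "sector", "pollutant", "height_bin", "period", "tons")
}
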
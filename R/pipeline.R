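# Pipeline orchestration: configuration, shared synthetic inputs, per-scenario
# runs (generate -> downscale -> air quality -> equity -> health), scenario
# comparison, and plain-text artifact writing with a run manifest.

#' Pipeline run configuration
#'
#' Bundles every knob of the pipeline behind a single validated object. One
#' root seed deterministically spawns per-module sub-streams, so the whole
#' run is reproducible while modules stay independently testable.
#'
#' @param seed Root integer seed.
#' @param n_regions,counties_per_region,domain_size Geography, see
#'   [gen_counties()].
#' @param base_population National 2020 population, persons.
#' @param trajectory A [demographic_trajectory()].
#' @param n_clusters,units_per_cluster EGU fleet size, see [gen_egu_fleet()].
#' @param initial_stock,zev_share_2020,lifetime Vehicle fleet, see
#'   [init_vehicle_stock()] and [fleet_turnover()].
#' @param scenarios Scenario names to run (subset of [aq_scenarios()]).
#' @param variants Health-estimate variants, subset of `c("A","B","C")`.
#' @param emissions An [emissions_config()].
#' @param met An [met_config()].
#' @param frac_so2_to_so4,frac_nox_to_hno3,ammonia_umol Chemistry, see
#'   [chem_config()].
#' @param baseline_multiplier All-sector scale-up of the 2020 modelled
#'   emissions used as the chemistry baseline inventory.
#' @param rr_constant,beta_multipliers Health risk configuration, see
#'   [rr_config()].
#' @param quantile_type Weighted-quantile convention for exposure summaries.
#' @return Object of class `aq_run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_regions = 9L,
                       counties_per_region = 6L,
                       domain_size = 1000,
                       base_population = 1e7,
                       trajectory = demographic_trajectory(),
                       n_clusters = 18L,
                       units_per_cluster = 3L,
                       initial_stock = c(light_duty = 8e6, medium_heavy_duty = 8e5),
                       zev_share_2020 = 0.02,
                       lifetime = 3L,
                       scenarios = aq_scenarios(),
                       variants = c("A", "B", "C"),
                       emissions = emissions_config(),
                       met = met_config(),
                       frac_so2_to_so4 = 0.2,
                       frac_nox_to_hno3 = 0.15,
                       ammonia_umol = 3,
                       baseline_multiplier = 3,
                       rr_constant = 1.06,
                       beta_multipliers = c(
                         black_nh = 3, white_nh = 0.9,
                         hispanic = 1.2, other = 1.1
                       ),
                       quantile_type = "step") {
  check_scalar_number(seed, "seed", integerish = TRUE)
  if (length(scenarios) == 0L) {
    abort_invalid("`scenarios` must name at least one scenario.")
  }
  bad <- setdiff(scenarios, aq_scenarios())
  if (length(bad)) {
    abort_invalid(sprintf("Unknown scenario(s): %s.", paste(bad, collapse = ", ")))
  }
  cfg <- structure(
    list(
      seed = as.integer(seed), n_regions = n_regions,
      counties_per_region = counties_per_region, domain_size = domain_size,
      base_population = base_population, trajectory = trajectory,
      n_clusters = n_clusters, units_per_cluster = units_per_cluster,
      initial_stock = initial_stock, zev_share_2020 = zev_share_2020,
      lifetime = lifetime, scenarios = scenarios, variants = variants,
      emissions = emissions, met = met,
      chem_params = list(
        frac_so2_to_so4 = frac_so2_to_so4,
        frac_nox_to_hno3 = frac_nox_to_hno3,
        ammonia_umol = ammonia_umol
      ),
      baseline_multiplier = baseline_multiplier,
      rr_constant = rr_constant, beta_multipliers = beta_multipliers,
      quantile_type = quantile_type
    ),
    class = "aq_run_config"
  )
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads a YAML mapping whose keys mirror the [run_config()] arguments
#' (nested `trajectory`, `emissions` and `met` sections are passed to their
#' constructors) and validates it.
#'
#' @param path YAML file path.
#' @return An `aq_run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$trajectory)) {
    traj_args <- y$trajectory
    if (!is.null(traj_args$group_share_anchors)) {
      traj_args$group_share_anchors <-
        as_tibble(purrr::map_dfr(traj_args$group_share_anchors, as_tibble))
    }
    args$trajectory <- do.call(demographic_trajectory, traj_args)
  }
  if (!is.null(y$emissions)) args$emissions <- do.call(emissions_config, y$emissions)
  if (!is.null(y$met)) args$met <- do.call(met_config, y$met)
  for (nm in c("initial_stock", "beta_multipliers")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(run_config, args)
}

#' Generate the shared synthetic inputs of a run
#'
#' Everything that does not depend on the policy scenario: geography,
#' population projection, EGU fleet, VMT surrogate, unit generation shares,
#' the chemistry baseline inventory (anchored on the current-policy 2020
#' emissions), and the source-receptor set.
#'
#' @param config An [run_config()].
#' @return List of class `aq_pipeline_inputs`.
#' @export
generate_inputs <- function(config) {
  if (!inherits(config, "aq_run_config")) {
    abort_invalid("`config` must be a run_config().")
  }
  counties <- gen_counties(
    config$n_regions, config$counties_per_region,
    config$domain_size, module_seed(config$seed, "geography")
  )
  population <- gen_population(
    counties, config$trajectory, config$base_population,
    module_seed(config$seed, "population")
  )
  fleet <- gen_egu_fleet(
    counties, config$n_clusters, config$units_per_cluster,
    module_seed(config$seed, "egu")
  )
  surrogate <- gen_vmt_surrogate(
    counties, population, module_seed(config$seed, "vmt")
  )
  shares <- unit_generation_shares(fleet)
  chem <- chem_config(
    config$chem_params$frac_so2_to_so4,
    config$chem_params$frac_nox_to_hno3,
    config$chem_params$ammonia_umol
  )

  # Baseline inventory: current-policy 2020 county emissions scaled to stand
  # for all sources; the SR set is then fixed for every scenario.
  cp <- policy_schedule("current_policy")
  stock_cp <- fleet_turnover(cp, init_vehicle_stock(
    config$initial_stock, config$zev_share_2020
  ), lifetime = config$lifetime)
  regional_cp <- gen_regional_emissions(
    cp, stock_cp, fleet, surrogate, counties, config$emissions
  )
  county_2020 <- downscale_scenario(
    regional_cp |> filter(.data$period == 2020),
    shares, fleet, surrogate, counties, config, additions = NULL
  )
  baseline <- gen_baseline_inventory(county_2020, config$baseline_multiplier)
  sr <- build_sr_set(counties, baseline,
    met = config$met, chem = chem,
    pollutants = aq_pollutants(), height_bins = c("ground", "medium")
  )

  structure(
    list(
      counties = counties, population = population, fleet = fleet,
      surrogate = surrogate, shares = shares, chem = chem,
      baseline = baseline, sr = sr
    ),
    class = "aq_pipeline_inputs"
  )
}

# Downscale one scenario's regional emissions (all periods present) to
# counties: EGU path (clusters + optional grow-in-place additions for the
# electrification increment) plus the VMT-surrogate path for on-road rows.
downscale_scenario <- function(regional, shares, fleet, surrogate, counties,
                               config, additions = NULL) {
  fleet_r <- fleet |>
    left_join(select(counties, "county_id", "region_id"), by = "county_id")

  needs_sites <- any(regional$technology == "gas_new" & regional$tons > 0)
  if (needs_sites && is.null(additions)) {
    # Site the peak incremental fossil generation once; the per-period split
    # is proportional, so one siting serves every period.
    ef_gas_nox <- config$emissions$egu_ef |>
      filter(.data$fuel == "gas", .data$pollutant == "nox") |>
      pull("tons_per_mwh")
    tons_per_mw <- max(ef_gas_nox, 1e-12) * 8760 *
      config$emissions$fossil_capacity_factor
    peak <- regional |>
      filter(.data$technology == "gas_new", .data$pollutant == "nox") |>
      summarise(tons = sum(.data$tons), .by = c("region_id", "period")) |>
      summarise(tons = max(.data$tons), .by = "region_id") |>
      filter(.data$tons > 0)
    new_capacity <- peak |>
      mutate(fuel = "gas", mw = .data$tons / tons_per_mw) |>
      select("region_id", "fuel", "mw")
    additions <- grow_in_place_allocate(new_capacity, fleet_r)
  }

  egu_county <- egu_emissions_to_counties(
    regional, shares, fleet, counties, additions
  )

  onroad <- regional |> filter(.data$sector == "onroad")
  onroad_county <- NULL
  if (nrow(onroad)) {
    periods <- sort(unique(onroad$period))
    onroad_county <- purrr::map_dfr(periods, function(t) {
      sub <- onroad |> filter(.data$period == t)
      # Downscale each technology's emissions with its vehicle type's
      # surrogate shares; treating emissions as the "VMT" conserves mass and
      # matches miles-based allocation exactly (factors are uniform within a
      # region-type).
      regional_as_vmt <- sub |>
        mutate(vehicle_type = sub("_ice$", "", .data$technology)) |>
        summarise(vmt = sum(.data$tons),
          .by = c("region_id", "vehicle_type", "pollutant")
        )
      purrr::map_dfr(unique(regional_as_vmt$pollutant), function(pol) {
        downscale_vmt(
          regional_as_vmt |> filter(.data$pollutant == pol),
          surrogate, counties, t
        ) |>
          mutate(pollutant = pol)
      })
    }) |>
      summarise(tons = sum(.data$vmt), .by = c("county_id", "pollutant", "period")) |>
      mutate(sector = "onroad", height_bin = "ground") |>
      select("county_id", "sector", "pollutant", "height_bin", "period", "tons")
  }

  bind_rows(egu_county, onroad_county) |>
    arrange(.data$period, .data$sector, .data$county_id, .data$pollutant)
}

#' Run one policy scenario end to end
#'
#' Generates (or reuses) the shared inputs, builds the scenario's schedule,
#' vehicle stock and regional emissions, downscales to counties, computes the
#' concentration field through the source-receptor set, and derives exposure
#' summaries and health results for every modelled period.
#'
#' @param config An [run_config()].
#' @param scenario Scenario name (must be in `config$scenarios`).
#' @param inputs Optional precomputed [generate_inputs()] result.
#' @param outdir Optional directory; when given, artifacts are written as CSV
#'   with a JSON run manifest.
#' @return Object of class `aq_scenario_run`.
#' @export
run_scenario <- function(config, scenario, inputs = NULL, outdir = NULL) {
  if (!scenario %in% aq_scenarios()) {
    abort_invalid(sprintf("Unknown scenario '%s'.", scenario))
  }
  if (is.null(inputs)) inputs <- generate_inputs(config)

  schedule <- policy_schedule(scenario)
  stock <- fleet_turnover(
    schedule,
    init_vehicle_stock(config$initial_stock, config$zev_share_2020),
    lifetime = config$lifetime
  )
  regional <- gen_regional_emissions(
    schedule, stock, inputs$fleet, inputs$surrogate, inputs$counties,
    config$emissions
  )
  county_emissions <- downscale_scenario(
    regional, inputs$shares, inputs$fleet, inputs$surrogate,
    inputs$counties, config
  )
  field <- total_pm_field(county_emissions, inputs$sr)
  exposure <- exposure_summary(field, inputs$population,
    type = config$quantile_type
  )
  deaths <- scenario_deaths(field, inputs$population,
    variants = config$variants,
    rr_constant = config$rr_constant,
    beta_multipliers = config$beta_multipliers
  )

  structure(
    list(
      scenario = scenario, config = config,
      regional_emissions = regional, county_emissions = county_emissions,
      field = field, exposure = exposure, deaths = deaths,
      stock = stock
    ),
    class = "aq_scenario_run"
  )
}

#' @export
print.aq_scenario_run <- function(x, ...) {
  cat(sprintf(
    "<aq_scenario_run> %s: %d counties, %d periods, %d variants\n",
    x$scenario, dplyr::n_distinct(x$county_emissions$county_id),
    dplyr::n_distinct(x$field$period), dplyr::n_distinct(x$deaths$variant)
  ))
  invisible(x)
}

#' Run every configured scenario and compare
#'
#' @param config An [run_config()]; `"current_policy"` must be among the
#'   scenarios for avoided-deaths output.
#' @param inputs Optional precomputed inputs.
#' @param outdir Optional output directory passed through to
#'   [write_scenario_artifacts()].
#' @return Object of class `aq_run_set`: list of runs plus the
#'   [compare_scenarios()] comparison.
#' @export
run_pipeline <- function(config, inputs = NULL, outdir = NULL) {
  if (is.null(inputs)) inputs <- generate_inputs(config)
  runs <- purrr::map(
    stats::setNames(config$scenarios, config$scenarios),
    function(s) run_scenario(config, s, inputs = inputs)
  )
  comparison <- compare_scenarios(runs, inputs)
  out <- structure(
    list(runs = runs, comparison = comparison, inputs = inputs, config = config),
    class = "aq_run_set"
  )
  if (!is.null(outdir)) {
    for (r in runs) write_scenario_artifacts(r, file.path(outdir, r$scenario))
    write_comparison_artifacts(comparison, outdir)
  }
  out
}

#' Compare scenario runs against the current-policy baseline
#'
#' Produces the long comparison tables: population-weighted exposure and
#' disparity by scenario, group and period; exposure percentile
#' distributions; cumulative avoided-deaths ranges per scenario; and
#' per-capita deaths by race for a display year.
#'
#' @param runs Named list of `aq_scenario_run` objects including
#'   `current_policy`.
#' @param inputs The shared [generate_inputs()] object.
#' @param per_capita_period Display year for per-capita rates (default 2030).
#' @return Object of class `aq_comparison` with tibbles `exposure`,
#'   `avoided`, `per_capita`.
#' @export
compare_scenarios <- function(runs, inputs, per_capita_period = 2030) {
  if (length(runs) < 1L) abort_invalid("No scenario runs supplied.")
  if (!"current_policy" %in% names(runs)) {
    abort(
      "Scenario comparison requires a 'current_policy' run.",
      class = c("aqequity_missing_baseline", "aqequity_error")
    )
  }
  exposure <- purrr::imap_dfr(runs, function(r, nm) {
    mutate(as_tibble(r$exposure), scenario = nm, .before = 1)
  })
  baseline <- runs$current_policy$deaths
  avoided <- purrr::imap_dfr(
    runs[setdiff(names(runs), "current_policy")],
    function(r, nm) {
      mutate(avoided_deaths(r$deaths, baseline), scenario = nm, .before = 1)
    }
  )
  per_capita <- purrr::imap_dfr(runs, function(r, nm) {
    mutate(per_capita_deaths(r$deaths, inputs$population, per_capita_period),
      scenario = nm, period = per_capita_period, .before = 1
    )
  })
  structure(
    list(exposure = exposure, avoided = avoided, per_capita = per_capita),
    class = "aq_comparison"
  )
}

#' Write one scenario's artifacts as CSV with a JSON manifest
#'
#' All outputs are plain text; the manifest records the scenario, seed, a
#' configuration hash and the package version, so every artifact is traceable
#' to its configuration. Identical configuration and seed reproduce
#' byte-identical files.
#'
#' @param run An `aq_scenario_run`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_scenario_artifacts <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$county_emissions, file.path(outdir, "county_emissions.csv"))
  readr::write_csv(run$field, file.path(outdir, "concentration_field.csv"))
  readr::write_csv(as_tibble(run$exposure), file.path(outdir, "exposure_summary.csv"))
  readr::write_csv(as_tibble(run$deaths), file.path(outdir, "deaths.csv"))
  manifest <- list(
    scenario = run$scenario,
    seed = run$config$seed,
    config_hash = rlang::hash(run$config),
    package_version = as.character(utils::packageVersion("aqequity"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(outdir)
}

#' Write comparison tables as CSV
#' @param comparison An `aq_comparison`.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_comparison_artifacts <- function(comparison, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(comparison$exposure, file.path(outdir, "exposure_by_scenario.csv"))
  readr::write_csv(comparison$avoided, file.path(outdir, "avoided_deaths.csv"))
  readr::write_csv(comparison$per_capita, file.path(outdir, "per_capita_deaths.csv"))
  invisible(outdir)
}
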
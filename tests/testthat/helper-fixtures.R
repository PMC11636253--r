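# Shared fixtures, all built in code at test time.

# A small but internally consistent configuration: population, vehicle stock
# and generating fleet scaled together (1/5 of the default synthetic nation).
test_config <- function(seed = 42L, ...) {
  run_config(
    seed = seed,
    n_regions = 3L, counties_per_region = 4L, domain_size = 600,
    base_population = 2e6,
    n_clusters = 6L, units_per_cluster = 2L,
    initial_stock = c(light_duty = 1.6e6, medium_heavy_duty = 1.6e5),
    ...
  )
}

tiny_counties <- function(seed = 7L) gen_counties(2, 3, 300, seed)

# A hand-built two-county geography with known distances.
two_county_geo <- function() {
  tibble::tibble(
    county_id = c("A", "B"),
    region_id = c(1L, 1L),
    cx = c(0, 50), cy = c(0, 0),
    area = c(100, 100),
    pw_x = c(0, 50), pw_y = c(0, 0)
  )
}

# A bespoke policy schedule with explicit ZEV sales shares (used to exercise
# the cohort model against hand enumeration).
manual_schedule <- function(ld_shares) {
  periods <- aq_periods()
  stopifnot(length(ld_shares) == length(periods))
  structure(
    list(
      name = "current_policy",
      ces_clean_fraction = tibble::tibble(period = periods, fraction = 0),
      zev_sales_share = dplyr::bind_rows(
        tibble::tibble(vehicle_class = "light_duty", period = periods, share = ld_shares),
        tibble::tibble(vehicle_class = "medium_heavy_duty", period = periods, share = 0)
      ),
      carbon_tax = tibble::tibble(period = periods, usd_per_t = 0),
      netzero_cap_fraction = tibble::tibble(period = periods, fraction = 1)
    ),
    class = "aq_policy_schedule"
  )
}
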
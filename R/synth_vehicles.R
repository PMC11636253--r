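# Policy schedules and the vehicle stock-turnover cohort model.

#' Stylized policy schedule for a named scenario
#'
#' Encodes the six modelled policies as parameter schedules over the 2020-2050
#' periods:
#'
#' * `current_policy` — existing incentives only: a gentle decline in power
#'   sector fossil emissions and modest baseline ZEV adoption.
#' * `ces` — clean electricity standard: 80% clean generation in 2030 rising
#'   linearly to 100% in 2050 (effective 2030).
#' * `carbon_tax` — economy-wide tax rising linearly from $50/t CO2 in 2025 to
#'   $80/t in 2050 (effective 2025).
#' * `ice_ban` — zero-emission sales mandate: 80% of light-duty sales by 2030
#'   and 100% from 2035; 35% of medium/heavy-duty sales by 2030 rising
#'   linearly to 100% by 2045. Vehicles already on the road are unaffected.
#' * `ice_ban_ces` — both instruments combined.
#' * `net_zero` — emissions capped at a fraction of 2020 levels falling
#'   linearly from 1 (2020) to 0 (2050).
#'
#' Baseline ZEV sales shares (all scenarios) rise linearly from 5% (2020) to
#' 50% (2050) for light-duty and 2% to 30% for medium/heavy-duty vehicles;
#' mandate scenarios take the maximum of mandate and baseline, so shares are
#' nondecreasing.
#'
#' @param name One of [aq_scenarios()].
#' @return Object of class `aq_policy_schedule`: a list with `name`,
#'   `ces_clean_fraction` (tibble `period, fraction`), `zev_sales_share`
#'   (tibble `vehicle_class, period, share`), `carbon_tax` (tibble
#'   `period, usd_per_t`), and `netzero_cap_fraction` (tibble
#'   `period, fraction`).
#' @export
policy_schedule <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% aq_scenarios()) {
    abort_invalid(sprintf(
      "Unknown scenario '%s'; must be one of: %s.",
      paste(name, collapse = ","), paste(aq_scenarios(), collapse = ", ")
    ))
  }
  periods <- aq_periods()

  interp <- function(x0, y0, x1, y1, x) {
    pmin(pmax(y0 + (y1 - y0) * (x - x0) / (x1 - x0), pmin(y0, y1)), pmax(y0, y1))
  }

  ces_frac <- if (name %in% c("ces", "ice_ban_ces")) {
    ifelse(periods < 2030, 0, interp(2030, 0.8, 2050, 1.0, periods))
  } else {
    rep(0, length(periods))
  }

  baseline_ld <- interp(2020, 0.05, 2050, 0.50, periods)
  baseline_mh <- interp(2020, 0.02, 2050, 0.30, periods)
  zev_ld <- baseline_ld
  zev_mh <- baseline_mh
  if (name %in% c("ice_ban", "ice_ban_ces")) {
    mandate_ld <- ifelse(periods < 2030, 0,
      ifelse(periods == 2030, 0.8, 1.0)
    )
    mandate_mh <- ifelse(periods < 2030, 0, interp(2030, 0.35, 2045, 1.0, periods))
    zev_ld <- pmax(baseline_ld, mandate_ld)
    zev_mh <- pmax(baseline_mh, mandate_mh)
  }
  if (name == "net_zero") {
    ramp <- (periods - 2020) / 30
    zev_ld <- pmax(baseline_ld, ramp)
    zev_mh <- pmax(baseline_mh, ramp)
  }

  tax <- if (name == "carbon_tax") {
    ifelse(periods < 2025, 0, interp(2025, 50, 2050, 80, periods))
  } else {
    rep(0, length(periods))
  }

  cap <- if (name == "net_zero") 1 - (periods - 2020) / 30 else rep(1, length(periods))

  out <- structure(
    list(
      name = name,
      ces_clean_fraction = tibble(period = periods, fraction = ces_frac),
      zev_sales_share = bind_rows(
        tibble(vehicle_class = "light_duty", period = periods, share = zev_ld),
        tibble(vehicle_class = "medium_heavy_duty", period = periods, share = zev_mh)
      ),
      carbon_tax = tibble(period = periods, usd_per_t = tax),
      netzero_cap_fraction = tibble(period = periods, fraction = cap)
    ),
    class = "aq_policy_schedule"
  )
  validate_policy_schedule(out)
  out
}

validate_policy_schedule <- function(sched) {
  frac_ok <- function(x) all(x >= 0 & x <= 1)
  if (!frac_ok(sched$ces_clean_fraction$fraction) ||
    !frac_ok(sched$zev_sales_share$share) ||
    !frac_ok(sched$netzero_cap_fraction$fraction)) {
    abort_invalid("Schedule fractions must lie in [0, 1].")
  }
  if (is.unsorted(sched$ces_clean_fraction$fraction)) {
    abort_invalid("`ces_clean_fraction` must be nondecreasing.")
  }
  dec <- sched$zev_sales_share |>
    arrange(.data$period) |>
    summarise(bad = is.unsorted(.data$share), .by = "vehicle_class") |>
    filter(.data$bad)
  if (nrow(dec)) {
    abort_invalid("`zev_sales_share` must be nondecreasing per vehicle class.")
  }
  invisible(sched)
}

#' Initial (2020) vehicle stock
#'
#' Splits the 2020 stock of each class into three equal age cohorts (vintages
#' 2010, 2015, 2020); the ZEV share applies to the 2020 cohort only, so the
#' pre-2020 fleet is all-ICE.
#'
#' @param counts Named vector of total 2020 stock by vehicle class.
#' @param zev_share_2020 ZEV fraction of the 2020 cohort.
#' @return Tibble `vehicle_class, technology, vintage_period, count`.
#' @export
init_vehicle_stock <- function(counts = c(light_duty = 8e6, medium_heavy_duty = 8e5),
                               zev_share_2020 = 0.02) {
  if (any(counts < 0)) abort_invalid("Stock counts must be nonnegative.")
  purrr::imap_dfr(counts, function(total, cls) {
    per <- total / 3
    tibble(
      vehicle_class = cls,
      technology = c("ice", "ice", "ice", "zev"),
      vintage_period = c(2010L, 2015L, 2020L, 2020L),
      count = c(per, per, per * (1 - zev_share_2020), per * zev_share_2020)
    )
  })
}

#' Vehicle stock turnover under a sales-share policy
#'
#' Cohort survival model on five-year periods. A cohort of vintage `v`
#' survives through period `v + 5 * lifetime` inclusive and retires at the
#' following period, so existing vehicles are never removed by a sales
#' mandate: with a 100% ZEV sales share from period `T`, the ICE stock reaches
#' exactly zero at period `T + 5 * lifetime`. New sales in each period after
#' 2020 are split between ICE and ZEV by the schedule's sales share.
#'
#' @param schedule An [policy_schedule()] object.
#' @param initial_stock Tibble from [init_vehicle_stock()] (the 2020 cohorts).
#' @param lifetime Vehicle lifetime in five-year periods (default 3, i.e. 15
#'   years of service after the vintage period).
#' @param sales_per_period Named vector of sales per period by vehicle class,
#'   or `NULL` to default to one third of each class's initial stock (steady
#'   replacement).
#'
#' @return Tibble `vehicle_class, technology, vintage_period, period, count`
#'   giving the surviving stock in every modelled period.
#' @export
fleet_turnover <- function(schedule, initial_stock, lifetime = 3,
                           sales_per_period = NULL) {
  if (!inherits(schedule, "aq_policy_schedule")) {
    abort_invalid("`schedule` must be a policy_schedule().")
  }
  check_scalar_number(lifetime, "lifetime", positive = TRUE, integerish = TRUE)
  check_columns(initial_stock, c("vehicle_class", "technology", "vintage_period", "count"),
    "initial_stock"
  )
  if (any(initial_stock$count < 0)) abort_invalid("Initial stock counts must be >= 0.")

  classes <- unique(initial_stock$vehicle_class)
  if (is.null(sales_per_period)) {
    totals <- initial_stock |> summarise(n = sum(.data$count), .by = "vehicle_class")
    sales_per_period <- stats::setNames(totals$n / 3, totals$vehicle_class)
  }
  if (any(sales_per_period < 0)) abort_invalid("`sales_per_period` must be >= 0.")

  shares <- schedule$zev_sales_share
  periods <- aq_periods()

  cohorts <- initial_stock
  new_sales <- purrr::map_dfr(periods[periods > 2020], function(t) {
    sh <- shares |> filter(.data$period == t)
    purrr::map_dfr(classes, function(cls) {
      s <- sh$share[sh$vehicle_class == cls]
      if (length(s) != 1L) {
        abort_structural(sprintf("Schedule lacks a ZEV share for %s at %d.", cls, t))
      }
      n <- sales_per_period[[cls]]
      tibble(
        vehicle_class = cls,
        technology = c("ice", "zev"),
        vintage_period = t,
        count = c(n * (1 - s), n * s)
      )
    })
  })
  cohorts <- bind_rows(cohorts, new_sales) |>
    summarise(count = sum(.data$count),
      .by = c("vehicle_class", "technology", "vintage_period")
    )

  purrr::map_dfr(periods, function(t) {
    cohorts |>
      filter(.data$vintage_period <= t,
        .data$vintage_period >= t - 5L * lifetime
      ) |>
      mutate(period = t)
  }) |>
    select("vehicle_class", "technology", "vintage_period", "period", "count") |>
    arrange(.data$period, .data$vehicle_class, .data$technology, .data$vintage_period)
}

# ICE fraction of the surviving stock per class and period.
ice_stock_share <- function(stock) {
  wide <- stock |>
    summarise(count = sum(.data$count),
      .by = c("vehicle_class", "technology", "period")
    ) |>
    tidyr::pivot_wider(names_from = "technology", values_from = "count",
      values_fill = 0
    )
  for (col in c("ice", "zev")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  wide |>
    mutate(
      total = .data$ice + .data$zev,
      ice_share = ifelse(.data$total > 0, .data$ice / .data$total, 0)
    ) |>
    select("vehicle_class", "period", "ice", "zev", "total", "ice_share")
}
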
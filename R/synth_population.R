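# Synthetic SSP2-like county population projection: heavy-tailed county
# sizes, race-ethnicity shares anchored nationally at 2020 and 2050, linear
# share interpolation between the anchors, and a fixed age pyramid per group.

#' Demographic trajectory (national anchors)
#'
#' National total growth to 2050 and race-ethnicity share anchors at 2020 and
#' 2050. Defaults follow a middle-of-the-road (SSP2-like) projection: +20%
#' total growth, the White non-Hispanic share falling from 60% to 48%, the
#' Hispanic share rising from 18% to 25%, the Black non-Hispanic share from
#' 13% to 14%, with the remainder in Other. Shares must sum to one at each
#' anchor.
#'
#' @param total_growth_2050 Fractional national growth from 2020 to 2050.
#' @param group_share_anchors Tibble with columns `group`, `share_2020`,
#'   `share_2050`.
#' @return An object of class `aq_demographic_trajectory`.
#' @export
demographic_trajectory <- function(
    total_growth_2050 = 0.20,
    group_share_anchors = tibble(
      group = aq_groups(),
      share_2020 = c(0.13, 0.60, 0.18, 0.09),
      share_2050 = c(0.14, 0.48, 0.25, 0.13)
    )) {
  check_scalar_number(total_growth_2050, "total_growth_2050")
  if (total_growth_2050 < -1) {
    abort_invalid("`total_growth_2050` must be >= -1.")
  }
  check_columns(group_share_anchors, c("group", "share_2020", "share_2050"),
    "group_share_anchors"
  )
  for (col in c("share_2020", "share_2050")) {
    s <- sum(group_share_anchors[[col]])
    if (abs(s - 1) > 1e-9) {
      abort_invalid(sprintf("Anchor shares in `%s` sum to %.12f, not 1.", col, s))
    }
  }
  structure(
    list(
      total_growth_2050 = total_growth_2050,
      group_share_anchors = group_share_anchors
    ),
    class = "aq_demographic_trajectory"
  )
}

# Fixed age pyramids (shares over the four bands, by group). White
# non-Hispanics skew oldest; Hispanic and Other groups youngest, which is
# what makes age-specific mortality rates matter for per-capita outcomes.
default_age_pyramid <- function() {
  tribble(
    ~group, ~age_band, ~share,
    "white_nh", "0-29", 0.30, "white_nh", "30-64", 0.44,
    "white_nh", "65-79", 0.18, "white_nh", "80+", 0.08,
    "black_nh", "0-29", 0.38, "black_nh", "30-64", 0.45,
    "black_nh", "65-79", 0.13, "black_nh", "80+", 0.04,
    "hispanic", "0-29", 0.45, "hispanic", "30-64", 0.44,
    "hispanic", "65-79", 0.08, "hispanic", "80+", 0.03,
    "other", "0-29", 0.42, "other", "30-64", 0.45,
    "other", "65-79", 0.10, "other", "80+", 0.03
  )
}

#' Generate a synthetic county population projection
#'
#' County 2020 totals are drawn from a heavy-tailed (log-normal) size
#' distribution so a few counties are dense. Per-county group shares are
#' noised around the national anchors and then rescaled so the national 2020
#' and 2050 group totals hit the trajectory anchors exactly; intermediate
#' periods interpolate the national group *shares* linearly while the national
#' total grows linearly to `(1 + growth) * base_total` at 2050. Age bands are
#' filled from a fixed per-group age pyramid.
#'
#' @param counties County tibble from [gen_counties()].
#' @param traj An [demographic_trajectory()] object.
#' @param base_total National 2020 population, persons.
#' @param seed Integer seed.
#' @param age_pyramid Optional tibble `group, age_band, share` overriding the
#'   default pyramid (shares must sum to 1 per group).
#'
#' @return Tibble `county_id, group, age_band, period, persons`.
#' @export
gen_population <- function(counties, traj, base_total, seed,
                           age_pyramid = default_age_pyramid()) {
  if (!inherits(traj, "aq_demographic_trajectory")) {
    abort_invalid("`traj` must be a demographic_trajectory().")
  }
  check_scalar_number(base_total, "base_total", positive = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)
  if (!is.data.frame(counties) || nrow(counties) == 0L) {
    abort_invalid("`counties` must be a non-empty county table.")
  }
  check_columns(counties, "county_id", "counties")
  check_columns(age_pyramid, c("group", "age_band", "share"), "age_pyramid")
  bad <- age_pyramid |>
    summarise(s = sum(.data$share), .by = "group") |>
    filter(abs(.data$s - 1) > 1e-9)
  if (nrow(bad)) abort_invalid("Age pyramid shares must sum to 1 per group.")

  anchors <- traj$group_share_anchors
  groups <- anchors$group
  n <- nrow(counties)
  growth <- traj$total_growth_2050

  withr::with_seed(seed, {
    w <- rlnorm(n, meanlog = 0, sdlog = 1.6)
    eps <- matrix(rnorm(n * length(groups), 0, 0.45),
      nrow = n,
      dimnames = list(counties$county_id, groups)
    )
  })
  w <- w / sum(w)

  # County x group matrices at the two anchor years: anchor share distorted by
  # a persistent county-level noise field, then each group column scaled so
  # the national group total matches the anchor exactly.
  anchor_matrix <- function(shares, total) {
    m <- sweep(exp(eps), 2, shares, `*`) * w
    targets <- shares * total
    sweep(m, 2, targets / colSums(m), `*`)
  }
  m2020 <- anchor_matrix(anchors$share_2020, base_total)
  m2050 <- anchor_matrix(anchors$share_2050, base_total * (1 + growth))

  periods <- aq_periods()
  by_period <- purrr::map(periods, function(t) {
    f <- (t - 2020) / 30
    share_t <- (1 - f) * anchors$share_2020 + f * anchors$share_2050
    total_t <- base_total * (1 + growth * f)
    raw <- (1 - f) * m2020 + f * m2050
    m <- sweep(raw, 2, (share_t * total_t) / colSums(raw), `*`)
    tibble(
      county_id = rep(rownames(m), times = length(groups)),
      group = rep(groups, each = n),
      period = t,
      persons = as.vector(m)
    )
  })

  bind_rows(by_period) |>
    inner_join(age_pyramid, by = "group", relationship = "many-to-many") |>
    mutate(persons = .data$persons * .data$share) |>
    select("county_id", "group", "age_band", "period", "persons") |>
    arrange(.data$period, .data$county_id, .data$group, .data$age_band)
}
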
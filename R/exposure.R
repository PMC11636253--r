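# Population-weighted exposure, the disparity statistic, and
# population-weighted exposure distributions by race-ethnicity group.

# Total concentration per county for one period (sectors summed).
field_slice <- function(field, period) {
  check_columns(field, c("county_id", "period", "conc"), "field")
  field |>
    filter(.data$period == .env$period) |>
    summarise(conc = sum(.data$conc), .by = "county_id")
}

group_pop_slice <- function(pop, group, period) {
  check_columns(pop, c("county_id", "group", "period", "persons"), "pop")
  sub <- pop |> filter(.data$period == .env$period)
  if (!identical(group, "total")) {
    sub <- sub |> filter(.data$group == .env$group)
  }
  sub |> summarise(persons = sum(.data$persons), .by = "county_id")
}

#' Population-weighted exposure
#'
#' Mean concentration experienced by a group: every person is assigned their
#' county's concentration, so the group mean is the county concentration
#' weighted by the group's county populations.
#'
#' @param field Concentration field tibble (`county_id, period, conc`, any
#'   sector attribution summed).
#' @param pop Population table.
#' @param group A race-ethnicity group code or `"total"` for the whole
#'   population.
#' @param period Modelled period.
#' @return Scalar, ug/m^3.
#' @export
pw_exposure <- function(field, pop, group = "total", period) {
  f <- field_slice(field, period)
  p <- group_pop_slice(pop, group, period)
  joined <- inner_join(f, p, by = "county_id")
  total_pop <- sum(joined$persons)
  if (total_pop <= 0) {
    abort(sprintf("Group '%s' has zero population in %s.", group, period),
      class = c("aqequity_undefined_exposure", "aqequity_error")
    )
  }
  sum(joined$conc * joined$persons) / total_pop
}

#' Exposure disparity for a group
#'
#' The group's population-weighted exposure minus the total population's
#' population-weighted exposure; negative values mean below-average exposure.
#' Weighted by group populations, disparities sum to zero by construction.
#'
#' @inheritParams pw_exposure
#' @return Scalar, ug/m^3 (may be negative).
#' @export
exposure_disparity <- function(field, pop, group, period) {
  pw_exposure(field, pop, group, period) - pw_exposure(field, pop, "total", period)
}

#' Weighted quantile
#'
#' Population-weighted quantile of county values. The default `"step"`
#' convention returns the smallest value whose cumulative normalized weight
#' reaches `q` (inclusive CDF, matching a direct enumeration of the weighted
#' CDF); the `"midpoint"` convention interpolates linearly between values at
#' their midpoint cumulative weights.
#'
#' @param values Numeric values.
#' @param weights Nonnegative weights, not all zero.
#' @param q Quantile(s) in `[0, 1]`.
#' @param type `"step"` (default) or `"midpoint"`.
#' @return Quantile value(s).
#' @export
weighted_quantile <- function(values, weights, q, type = c("step", "midpoint")) {
  type <- match.arg(type)
  if (length(values) != length(weights)) {
    abort_invalid("`values` and `weights` must have equal length.")
  }
  if (any(weights < 0)) abort_invalid("`weights` must be >= 0.")
  if (sum(weights) <= 0) abort_invalid("`weights` must not be all zero.")
  if (any(q < 0 | q > 1)) abort_invalid("`q` must lie in [0, 1].")
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord]
  cw <- cumsum(w) / sum(w)
  if (type == "step") {
    vapply(q, function(qi) v[which(cw >= qi - 1e-12)[1]], numeric(1))
  } else {
    mid <- (cumsum(w) - w / 2) / sum(w)
    vapply(q, function(qi) {
      if (qi <= mid[1]) return(v[1])
      if (qi >= mid[length(mid)]) return(v[length(v)])
      stats::approx(mid, v, xout = qi, ties = "ordered")$y
    }, numeric(1))
  }
}

#' Exposure summary by group and period
#'
#' Tidy table of population-weighted exposure, disparity, and
#' population-weighted exposure quantiles for every group (plus `"total"`)
#' and period covered by the field.
#'
#' @param field Concentration field tibble.
#' @param pop Population table.
#' @param quantiles Quantile probabilities reported (default the 10th, 25th,
#'   50th, 75th and 90th percentiles).
#' @param type Weighted-quantile convention, see [weighted_quantile()].
#' @return Tibble of class `aq_exposure_summary`: `period, group, metric,
#'   value` with metrics `pw_exposure`, `disparity` and `q<percentile>`.
#' @export
exposure_summary <- function(field, pop,
                             quantiles = c(0.1, 0.25, 0.5, 0.75, 0.9),
                             type = "step") {
  periods <- sort(unique(field$period))
  groups <- c(unique(pop$group), "total")
  out <- purrr::map_dfr(periods, function(t) {
    f <- field_slice(field, t)
    total_pw <- pw_exposure(field, pop, "total", t)
    purrr::map_dfr(groups, function(g) {
      p <- group_pop_slice(pop, g, t)
      joined <- inner_join(f, p, by = "county_id")
      pw <- sum(joined$conc * joined$persons) / sum(joined$persons)
      qv <- weighted_quantile(joined$conc, joined$persons, quantiles, type = type)
      bind_rows(
        tibble(period = t, group = g, metric = "pw_exposure", value = pw),
        tibble(period = t, group = g, metric = "disparity", value = pw - total_pw),
        tibble(
          period = t, group = g,
          metric = sprintf("q%02d", round(quantiles * 100)), value = qv
        )
      )
    })
  })
  class(out) <- c("aq_exposure_summary", class(out))
  out
}
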
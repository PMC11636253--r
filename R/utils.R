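# Shared vocabulary and small helpers used across the pipeline.

#' Modelled five-year periods
#'
#' The analysis horizon runs 2020--2050 in five-year steps; each period's
#' result represents every calendar year in the half-decade it opens (2050
#' stands alone, closing the horizon at 31 years).
#'
#' @return Integer vector `c(2020, 2025, ..., 2050)`.
#' @export
aq_periods <- function() seq(2020L, 2050L, by = 5L)

#' Race-ethnicity groups tracked by the pipeline
#'
#' Four mutually exclusive groups: Black non-Hispanic, White non-Hispanic,
#' Hispanic (any race), and Other.
#'
#' @return Character vector of group codes.
#' @export
aq_groups <- function() c("black_nh", "white_nh", "hispanic", "other")

#' Age bands of the population table
#'
#' Mortality is applied to adults 30 and older; the youngest band exists so
#' per-capita rates can be reported against the whole population.
#'
#' @return Character vector of age-band labels.
#' @export
aq_age_bands <- function() c("0-29", "30-64", "65-79", "80+")

#' Age bands entering the concentration-response function
#' @return Character vector (ages 30+).
#' @export
aq_adult_bands <- function() c("30-64", "65-79", "80+")

#' Modelled pollutants
#' @return Character vector: NOx, SO2 and primary PM2.5.
#' @export
aq_pollutants <- function() c("nox", "so2", "pm25")

#' Modelled policy scenarios
#' @return Character vector of the six scenario names.
#' @export
aq_scenarios <- function() {
  c("current_policy", "ces", "carbon_tax", "ice_ban", "ice_ban_ces", "net_zero")
}

# Years each period stands for when accumulating annual quantities over the
# 2020-2050 horizon: five for 2020..2045, one for 2050 (31 years total).
period_year_weights <- function(periods = aq_periods()) {
  w <- ifelse(periods == 2050L, 1, 5)
  stats::setNames(w, periods)
}

abort_invalid <- function(msg) {
  abort(msg, class = c("aqequity_invalid_argument", "aqequity_error"))
}

abort_structural <- function(msg) {
  abort(msg, class = c("aqequity_structural_error", "aqequity_error"))
}

check_scalar_number <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort_invalid(sprintf("`%s` must be positive.", name))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_invalid(sprintf("`%s` must be a whole number.", name))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_structural(sprintf(
      "`%s` is missing required column(s): %s.", name,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Derive a reproducible sub-seed for a named module stream from the root seed.
# Kept well below .Machine$integer.max for 32-bit safety.
module_seed <- function(seed, stream) {
  offsets <- c(
    geography = 101L, population = 211L, egu = 307L, vmt = 401L,
    vehicles = 503L, emissions = 601L, baseline = 701L
  )
  if (!stream %in% names(offsets)) {
    abort_structural(sprintf("Unknown seed stream '%s'.", stream))
  }
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stream]]
}
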
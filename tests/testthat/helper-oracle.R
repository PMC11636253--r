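# Independent brute-force implementations used as oracles. These deliberately
# share no code with the package: plain loops and direct transcriptions of
# the closed forms.

oracle_sigma_z <- function(x, a = 0.06, b = 0.0015, cc = 0.5) {
  a * x / (1 + b * x)^cc
}

oracle_kernel_point <- function(x_m, H, u = 4, f = 1 / 16, zmix = 1000,
                                a = 0.06, b = 0.0015, cc = 0.5) {
  q <- 907184.74 / 3.15576e7
  s <- oracle_sigma_z(x_m, a, b, cc)
  arc <- 2 * pi * x_m / 16
  direct <- 2 * q * f / (sqrt(2 * pi) * s * u * arc) * exp(-H^2 / (2 * s^2))
  cap <- q * f / (arc * zmix * u)
  min(direct, cap) * 1e6
}

# Full-field oracle: double loop over sources and receptors, ground + medium
# release heights, receptor-side chemistry. `emissions` is a tibble
# county_id / pollutant / height_bin / tons.
oracle_field_total <- function(emissions, counties,
                               frac_so4 = 0.2, frac_hno3 = 0.15, ammonia = 3,
                               heights = c(ground = 0, low = 125, medium = 375, tall = 750)) {
  n <- nrow(counties)
  conc <- list(pm25 = rep(0, n), so2 = rep(0, n), nox = rep(0, n))
  for (r in seq_len(n)) {
    for (i in seq_len(nrow(emissions))) {
      s_idx <- match(emissions$county_id[i], counties$county_id)
      dx <- (counties$pw_x[r] - counties$pw_x[s_idx]) * 1000
      dy <- (counties$pw_y[r] - counties$pw_y[s_idx]) * 1000
      d <- sqrt(dx^2 + dy^2)
      floor_m <- 0.5 * sqrt(counties$area[s_idx] / pi) * 1000
      d <- max(d, floor_m)
      h <- heights[[emissions$height_bin[i]]]
      p <- emissions$pollutant[i]
      conc[[p]][r] <- conc[[p]][r] +
        emissions$tons[i] * oracle_kernel_point(d, h)
    }
  }
  total <- numeric(n)
  for (r in seq_len(n)) {
    s_mol <- conc$so2[r] / 64 * frac_so4
    n_dem <- conc$nox[r] / 46 * frac_hno3
    free <- max(0, ammonia - 2 * s_mol)
    s_pm <- s_mol * if (ammonia >= 2 * s_mol) 132 else 98
    n_pm <- min(n_dem, free) * 80
    total[r] <- conc$pm25[r] + s_pm + n_pm
  }
  total
}

# Weighted-quantile oracle: enumerate the cumulative weighted CDF and return
# the smallest value reaching q.
oracle_weighted_quantile <- function(values, weights, q) {
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord]) / sum(weights)
  v[which(cw >= q)[1]]
}

# Cohort-model oracle: replay sales and survival period by period.
oracle_ice_stock <- function(shares_by_period, initial_ice, initial_vintage,
                             sales, lifetime) {
  periods <- aq_periods()
  cohorts <- data.frame(vintage = initial_vintage, ice = initial_ice)
  for (t in periods[periods > 2020]) {
    s <- shares_by_period[[as.character(t)]]
    cohorts <- rbind(cohorts, data.frame(vintage = t, ice = sales * (1 - s)))
  }
  sapply(periods, function(t) {
    alive <- cohorts$vintage <= t & cohorts$vintage >= t - 5 * lifetime
    sum(cohorts$ice[alive])
  })
}
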
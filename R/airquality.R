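# Reduced-complexity atmospheric model: annual-average sector-averaged
# Gaussian plume kernels by effective-height bin, simplified
# ammonium-nitrate-sulfate partitioning against a fixed baseline inventory,
# the add-one-ton marginal-concentration algorithm, and linear totalization
# of emissions times marginal concentrations.

GRAMS_PER_SHORT_TON <- 907184.74
SECONDS_PER_YEAR <- 3.15576e7

# Molar masses, g/mol.
MW <- c(so2 = 64, no2 = 46, so4 = 96, no3 = 62, amso4 = 132, amno3 = 80)

#' Meteorological configuration for the plume kernel
#'
#' A single annual climatology: a 16-sector wind rose, one transport speed, a
#' Briggs-style rural neutral-stability vertical-dispersion closure
#' `sigma_z(x) = a x / (1 + b x)^c`, a mixing height capping vertical spread,
#' and representative release heights for the four effective-height bins
#' (ground for transport; low/medium/tall point-source bins, with medium --
#' 250-500 m effective height -- the default for power plants).
#'
#' @param sector_freq 16 wind-sector frequencies summing to one (default
#'   uniform).
#' @param wind_speed Transport wind speed, m/s.
#' @param sigma_z_coeffs Named vector `c(a, b, c)` of the dispersion closure.
#' @param mixing_height Boundary-layer mixing height, m.
#' @param bin_heights Named vector of effective release heights, m.
#' @param calibration Multiplicative calibration scalar applied to every
#'   kernel value (monitor calibration stand-in; default 1).
#' @return Object of class `aq_met_config`.
#' @export
met_config <- function(sector_freq = rep(1 / 16, 16),
                       wind_speed = 4,
                       sigma_z_coeffs = c(a = 0.06, b = 0.0015, c = 0.5),
                       mixing_height = 1000,
                       bin_heights = c(ground = 0, low = 125, medium = 375, tall = 750),
                       calibration = 1) {
  if (length(sector_freq) != 16L || any(sector_freq < 0) ||
    abs(sum(sector_freq) - 1) > 1e-9) {
    abort_invalid("`sector_freq` must be 16 nonnegative frequencies summing to 1.")
  }
  check_scalar_number(wind_speed, "wind_speed", positive = TRUE)
  check_scalar_number(mixing_height, "mixing_height", positive = TRUE)
  check_scalar_number(calibration, "calibration", positive = TRUE)
  structure(
    list(
      sector_freq = sector_freq, wind_speed = wind_speed,
      sigma_z_coeffs = sigma_z_coeffs, mixing_height = mixing_height,
      bin_heights = bin_heights, calibration = calibration
    ),
    class = "aq_met_config"
  )
}

#' Chemistry configuration for inorganic PM partitioning
#'
#' Receptor-side conversion fractions for the two PM precursors and a
#' county-level ammonia budget (micromol per cubic metre of air available to
#' neutralize acids). Sulfate always forms particle mass -- as ammonium
#' sulfate when free ammonia suffices, otherwise as sulfuric acid -- and
#' nitrate forms ammonium nitrate only from ammonia left over after sulfate
#' is neutralized.
#'
#' @param frac_so2_to_so4 Fraction of dispersed SO2 converted to sulfate.
#' @param frac_nox_to_hno3 Fraction of dispersed NOx converted to nitric acid
#'   (nitrate demand).
#' @param ammonia_umol Ammonia budget, umol/m^3: a single number (applied to
#'   every county) or a vector named by county id.
#' @return Object of class `aq_chem_config`.
#' @export
chem_config <- function(frac_so2_to_so4 = 0.2,
                        frac_nox_to_hno3 = 0.15,
                        ammonia_umol = 3) {
  for (f in c(frac_so2_to_so4, frac_nox_to_hno3)) {
    if (!is.numeric(f) || f < 0 || f > 1) {
      abort_invalid("Conversion fractions must lie in [0, 1].")
    }
  }
  if (any(ammonia_umol < 0)) abort_invalid("Ammonia budgets must be >= 0.")
  structure(
    list(
      frac_so2_to_so4 = frac_so2_to_so4,
      frac_nox_to_hno3 = frac_nox_to_hno3,
      ammonia_umol = ammonia_umol,
      molar_mass = MW
    ),
    class = "aq_chem_config"
  )
}

#' Vertical dispersion coefficient
#'
#' `sigma_z(x) = a x / (1 + b x)^c`, with downwind distance `x` in metres.
#' The default coefficients (a = 0.06, b = 0.0015, c = 0.5) describe rural
#' neutral-stability spreading and are monotone nondecreasing in `x`.
#'
#' @param x Downwind distance, m (strictly positive).
#' @param coeffs Named vector `c(a, b, c)`.
#' @return sigma_z in metres.
#' @export
sigma_z <- function(x, coeffs = c(a = 0.06, b = 0.0015, c = 0.5)) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort_invalid("`x` must be strictly positive.")
  }
  coeffs[["a"]] * x / (1 + coeffs[["b"]] * x)^coeffs[["c"]]
}

#' Sector-averaged annual Gaussian plume concentration
#'
#' Ground-level annual-average concentration at downwind distance `x` from a
#' steady point source, averaged over a 22.5-degree wind sector:
#' \deqn{C = \min\!\left( \frac{2 Q f_s}{\sqrt{2\pi}\,\sigma_z(x)\,u\,(2\pi x/16)}
#'   e^{-H^2/2\sigma_z(x)^2},\ \frac{Q f_s}{(2\pi x/16)\, z_{mix}\, u} \right)}
#' where `Q` is the emission rate converted from short tons per year to grams
#' per second, `f_s` the wind-sector frequency, `u` the wind speed, `H` the
#' effective release height, and the second limb a well-mixed boundary-layer
#' box that bounds the kernel. The result is returned in micrograms per cubic
#' metre.
#'
#' @param distance Downwind distance(s), m. Values below the caller's
#'   near-field floor should be clamped before calling (see
#'   [build_sr_set()]).
#' @param bearing_sector Integer wind sector 0-15 (used to look up `f_s`).
#' @param height_bin One of `"ground"`, `"low"`, `"medium"`, `"tall"`.
#' @param met An [met_config()].
#' @param emission_rate Source strength, short tons per year.
#' @return Concentration(s), micrograms per cubic metre.
#' @export
plume_kernel <- function(distance, bearing_sector = 0L, height_bin = "ground",
                         met = met_config(), emission_rate = 1) {
  if (any(emission_rate < 0)) abort_invalid("`emission_rate` must be >= 0.")
  if (!height_bin %in% names(met$bin_heights)) {
    abort_invalid(sprintf("Unknown height bin '%s'.", height_bin))
  }
  q_gs <- emission_rate * GRAMS_PER_SHORT_TON / SECONDS_PER_YEAR
  f_s <- met$sector_freq[(as.integer(bearing_sector) %% 16L) + 1L]
  h <- met$bin_heights[[height_bin]]
  sz <- sigma_z(distance, met$sigma_z_coeffs)
  arc <- 2 * pi * distance / 16
  direct <- 2 * q_gs * f_s / (sqrt(2 * pi) * sz * met$wind_speed * arc) *
    exp(-h^2 / (2 * sz^2))
  cap <- q_gs * f_s / (arc * met$mixing_height * met$wind_speed)
  pmin(direct, cap) * 1e6
}

# Near-field distance floor for a county acting as its own receptor (and for
# receptors closer than that): half the radius of the equal-area circle.
near_field_floor_m <- function(area_km2) {
  0.5 * sqrt(area_km2 / pi) * 1000
}

#' Plume kernel matrix between county centroids
#'
#' Dense source-by-receptor matrix of concentrations per one short ton per
#' year released in the given effective-height bin. Sources discharge from
#' and receptors sit at population-weighted county centroids; distances are
#' clamped below the near-field floor of the source county (half its
#' equal-area circle radius) to avoid the plume singularity at zero distance.
#' The calibration scalar of the met config multiplies every entry.
#'
#' @param counties County tibble from [gen_counties()].
#' @param height_bin Effective-height bin of the source.
#' @param met An [met_config()].
#' @return Matrix `[source county, receptor county]`, micrograms per cubic
#'   metre per short ton per year.
#' @export
kernel_matrix <- function(counties, height_bin = "ground", met = met_config()) {
  n <- nrow(counties)
  dx <- outer(counties$pw_x, counties$pw_x, function(a, b) b - a) * 1000
  dy <- outer(counties$pw_y, counties$pw_y, function(a, b) b - a) * 1000
  dist <- sqrt(dx^2 + dy^2)
  floor_m <- near_field_floor_m(counties$area)
  dist <- pmax(dist, matrix(floor_m, n, n))
  sector <- (floor(((atan2(dy, dx) %% (2 * pi)) / (2 * pi)) * 16)) %% 16
  k <- matrix(
    plume_kernel(as.vector(dist), as.vector(sector), height_bin, met, 1),
    n, n
  )
  k <- k * met$calibration
  dimnames(k) <- list(counties$county_id, counties$county_id)
  k
}

#' Partition sulfate and nitrate against an ammonia budget
#'
#' Simplified inorganic equilibrium: sulfate always forms particle mass, as
#' ammonium sulfate (mass factor 132/96 on sulfate mass) when ammonia is at
#' least 2 mol per mol sulfate, otherwise as sulfuric acid (98/96); free
#' ammonia after sulfate neutralization, `F = max(0, NH3 - 2 SO4)`, limits
#' ammonium nitrate, whose particle mass is `min(nitrate demand, F)` times
#' 80 g/mol.
#'
#' @param sulfate_mol Sulfate, umol/m^3.
#' @param nitrate_demand_mol Nitric-acid demand, umol/m^3.
#' @param ammonia_mol Ammonia budget, umol/m^3.
#' @return Tibble `sulfate_pm, nitrate_pm` in ug/m^3 (vectorized).
#' @export
partition_inorganic <- function(sulfate_mol, nitrate_demand_mol, ammonia_mol) {
  if (any(sulfate_mol < 0) || any(nitrate_demand_mol < 0) || any(ammonia_mol < 0)) {
    abort_invalid("All partitioning inputs must be >= 0.")
  }
  free <- pmax(0, ammonia_mol - 2 * sulfate_mol)
  sulfate_pm <- sulfate_mol * ifelse(ammonia_mol >= 2 * sulfate_mol, MW[["amso4"]], 98)
  nitrate_pm <- pmin(nitrate_demand_mol, free) * MW[["amno3"]]
  tibble(sulfate_pm = sulfate_pm, nitrate_pm = nitrate_pm)
}

# --- internal speciated-field machinery -----------------------------------

ammonia_vector <- function(chem, county_ids) {
  a <- chem$ammonia_umol
  if (length(a) == 1L && is.null(names(a))) {
    return(rep(a, length(county_ids)))
  }
  out <- a[county_ids]
  if (anyNA(out)) abort_structural("Ammonia budget missing for some counties.")
  unname(out)
}

# County emissions tibble (one period) -> named list of emission vectors
# indexed [pollutant][bin], aligned to county_ids.
emission_vectors <- function(emissions, county_ids) {
  out <- list()
  if (nrow(emissions) == 0L) return(out)
  combos <- emissions |> distinct(.data$pollutant, .data$height_bin)
  for (i in seq_len(nrow(combos))) {
    p <- combos$pollutant[i]
    b <- combos$height_bin[i]
    sub <- emissions |>
      filter(.data$pollutant == p, .data$height_bin == b) |>
      summarise(tons = sum(.data$tons), .by = "county_id")
    v <- stats::setNames(rep(0, length(county_ids)), county_ids)
    v[sub$county_id] <- sub$tons
    out[[p]][[b]] <- unname(v)
  }
  out
}

# Dispersed precursor concentrations (ug/m^3 of the emitted species) at every
# receptor, from emission vectors and per-bin kernel matrices.
dispersed_conc <- function(evec, kernels, n) {
  conc <- list(pm25 = rep(0, n), so2 = rep(0, n), nox = rep(0, n))
  for (p in names(evec)) {
    for (b in names(evec[[p]])) {
      if (is.null(kernels[[b]])) {
        abort_structural(sprintf("No kernel for height bin '%s'.", b))
      }
      conc[[p]] <- conc[[p]] + as.vector(crossprod(kernels[[b]], evec[[p]][[b]]))
    }
  }
  conc
}

# Full speciated field: primary PM plus receptor-side secondary formation.
speciated_field <- function(conc, ammonia, chem) {
  sulfate_mol <- conc$so2 / MW[["so2"]] * chem$frac_so2_to_so4
  nitrate_demand <- conc$nox / MW[["no2"]] * chem$frac_nox_to_hno3
  part <- partition_inorganic(sulfate_mol, nitrate_demand, ammonia)
  list(
    primary = conc$pm25,
    sulfate_pm = part$sulfate_pm,
    nitrate_pm = part$nitrate_pm,
    total = conc$pm25 + part$sulfate_pm + part$nitrate_pm
  )
}

#' Full PM2.5-equivalent field from a county emission inventory
#'
#' Direct (non-marginal) computation: disperses every pollutant from every
#' source county through the per-bin plume kernels and forms secondary
#' inorganic PM at the receptors against the county ammonia budgets.
#'
#' @param emissions County emissions tibble for one period (`county_id,
#'   pollutant, height_bin, tons`).
#' @param counties County tibble.
#' @param met,chem Model configurations.
#' @param kernels Optional precomputed kernel list (named by height bin) to
#'   avoid rebuilding.
#' @return Tibble `county_id, primary, sulfate_pm, nitrate_pm, total`
#'   (ug/m^3).
#' @export
pm_field_direct <- function(emissions, counties, met = met_config(),
                            chem = chem_config(), kernels = NULL) {
  ids <- counties$county_id
  bins <- unique(c("ground", emissions$height_bin))
  if (is.null(kernels)) {
    kernels <- lapply(stats::setNames(bins, bins), function(b) {
      kernel_matrix(counties, b, met)
    })
  }
  evec <- emission_vectors(emissions, ids)
  conc <- dispersed_conc(evec, kernels, length(ids))
  f <- speciated_field(conc, ammonia_vector(chem, ids), chem)
  tibble(
    county_id = ids, primary = f$primary, sulfate_pm = f$sulfate_pm,
    nitrate_pm = f$nitrate_pm, total = f$total
  )
}

#' Marginal concentrations of one source-pollutant pair
#'
#' The add-one-ton algorithm: compute the full speciated field from the
#' baseline inventory, add `add_tons` of the pollutant at the source county in
#' the given height bin, recompute, subtract, and normalize per ton; the
#' baseline is left untouched. For primary PM2.5 the result is the plume
#' kernel row (the model is linear in primary particles, independent of the
#' baseline); for SO2 and NOx it embeds the receptor ammonia regime fixed by
#' the baseline. Marginals are floored at zero, so sulfate displacing
#' nitrate at an ammonia-poor receptor cannot produce a negative entry.
#'
#' @param source_county Source county id.
#' @param pollutant One of [aq_pollutants()].
#' @param height_bin Effective-height bin of the release.
#' @param baseline Baseline county emissions tibble (the reference-year
#'   inventory).
#' @param counties County tibble.
#' @param met,chem Model configurations.
#' @param add_tons Perturbation size, short tons (default 1; 0 returns the
#'   zero vector).
#' @param kernels Optional precomputed kernel list.
#' @return Named numeric vector of ug/m^3 per short ton per year at every
#'   receptor county.
#' @export
marginal_concentrations <- function(source_county, pollutant, height_bin,
                                    baseline, counties, met = met_config(),
                                    chem = chem_config(), add_tons = 1,
                                    kernels = NULL) {
  if (!pollutant %in% aq_pollutants()) {
    abort_invalid(sprintf("Unknown pollutant '%s'.", pollutant))
  }
  ids <- counties$county_id
  if (!source_county %in% ids) {
    abort_invalid(sprintf("Unknown source county '%s'.", source_county))
  }
  if (add_tons == 0) {
    return(stats::setNames(rep(0, length(ids)), ids))
  }
  bins <- unique(c("ground", height_bin, baseline$height_bin))
  if (is.null(kernels)) {
    kernels <- lapply(stats::setNames(bins, bins), function(b) {
      kernel_matrix(counties, b, met)
    })
  }
  ammonia <- ammonia_vector(chem, ids)
  evec <- emission_vectors(baseline, ids)
  conc0 <- dispersed_conc(evec, kernels, length(ids))
  f0 <- speciated_field(conc0, ammonia, chem)

  conc1 <- conc0
  delta <- kernels[[height_bin]][source_county, ] * add_tons
  conc1[[pollutant]] <- conc1[[pollutant]] + delta
  f1 <- speciated_field(conc1, ammonia, chem)

  stats::setNames(pmax(0, (f1$total - f0$total) / add_tons), ids)
}

#' Build the full source-receptor set
#'
#' Runs the add-one-ton algorithm for every source county, pollutant, and
#' requested height bin against the fixed baseline inventory, storing dense
#' marginal-concentration matrices (source x receptor, ug/m^3 per short ton
#' per year).
#'
#' @param counties County tibble.
#' @param baseline Baseline county emissions tibble.
#' @param met,chem Model configurations.
#' @param pollutants Pollutants to cover.
#' @param height_bins Height bins to cover (default ground for transport and
#'   medium for power plants).
#' @return Object of class `aq_sr_set`: list with `matrices` (named
#'   `"<pollutant>.<bin>"`), `county_ids`, and the configurations.
#' @export
build_sr_set <- function(counties, baseline, met = met_config(),
                         chem = chem_config(),
                         pollutants = aq_pollutants(),
                         height_bins = c("ground", "medium")) {
  ids <- counties$county_id
  n <- length(ids)
  all_bins <- unique(c("ground", height_bins, baseline$height_bin))
  kernels <- lapply(stats::setNames(all_bins, all_bins), function(b) {
    kernel_matrix(counties, b, met)
  })
  ammonia <- ammonia_vector(chem, ids)
  evec <- emission_vectors(baseline, ids)
  conc0 <- dispersed_conc(evec, kernels, n)
  f0 <- speciated_field(conc0, ammonia, chem)

  matrices <- list()
  for (p in pollutants) {
    for (b in height_bins) {
      key <- paste(p, b, sep = ".")
      if (p == "pm25") {
        # Linear species: the marginal is the kernel row for any baseline.
        matrices[[key]] <- kernels[[b]]
        next
      }
      m <- matrix(0, n, n, dimnames = list(ids, ids))
      for (s in seq_len(n)) {
        conc1 <- conc0
        conc1[[p]] <- conc1[[p]] + kernels[[b]][s, ]
        f1 <- speciated_field(conc1, ammonia, chem)
        m[s, ] <- pmax(0, f1$total - f0$total)
      }
      matrices[[key]] <- m
    }
  }
  structure(
    list(matrices = matrices, county_ids = ids, met = met, chem = chem),
    class = "aq_sr_set"
  )
}

#' Total PM2.5-equivalent field from emissions and marginal concentrations
#'
#' Linear totalization: every receptor concentration is the sum over sources,
#' pollutants, and height bins of emissions times the marginal concentration,
#' keeping source-sector attribution.
#'
#' @param emissions County emissions tibble (`county_id, sector, pollutant,
#'   height_bin, period, tons`).
#' @param sr An [build_sr_set()] object covering every source x pollutant x
#'   bin with nonzero emissions.
#' @return Tibble `county_id, period, sector, conc` (ug/m^3,
#'   PM2.5-equivalent).
#' @export
total_pm_field <- function(emissions, sr) {
  if (!inherits(sr, "aq_sr_set")) abort_invalid("`sr` must be an aq_sr_set.")
  ids <- sr$county_ids
  nz <- emissions |> filter(.data$tons > 0)
  bad_county <- setdiff(unique(nz$county_id), ids)
  if (length(bad_county)) {
    abort_structural(sprintf(
      "Source county not covered by the SR set: %s.",
      paste(bad_county, collapse = ", ")
    ))
  }
  groups <- emissions |> distinct(.data$period, .data$sector)
  out <- purrr::pmap_dfr(groups, function(period, sector) {
    sub <- nz |>
      filter(.data$period == .env$period, .data$sector == .env$sector)
    conc <- rep(0, length(ids))
    combos <- sub |> distinct(.data$pollutant, .data$height_bin)
    for (i in seq_len(nrow(combos))) {
      key <- paste(combos$pollutant[i], combos$height_bin[i], sep = ".")
      m <- sr$matrices[[key]]
      if (is.null(m)) {
        abort_structural(sprintf("SR set lacks an entry for '%s'.", key))
      }
      ev <- sub |>
        filter(.data$pollutant == combos$pollutant[i],
          .data$height_bin == combos$height_bin[i]
        ) |>
        summarise(tons = sum(.data$tons), .by = "county_id")
      v <- stats::setNames(rep(0, length(ids)), ids)
      v[ev$county_id] <- ev$tons
      conc <- conc + as.vector(crossprod(m, v))
    }
    tibble(county_id = ids, period = period, sector = sector, conc = conc)
  })
  arrange(out, .data$period, .data$sector, .data$county_id)
}

#' Synthetic baseline (reference-year) inventory
#'
#' Stand-in for the all-sector reference inventory the nonlinear chemistry is
#' anchored to: the modelled sectors' emissions in the anchor period scaled
#' up by a multiplier representing all other sources.
#'
#' @param county_emissions County emissions tibble covering `anchor_period`.
#' @param multiplier All-sector scale-up factor (default 3).
#' @param anchor_period Period whose emissions anchor the baseline.
#' @return County emissions tibble (no `period` column).
#' @export
gen_baseline_inventory <- function(county_emissions, multiplier = 3,
                                   anchor_period = 2020) {
  check_scalar_number(multiplier, "multiplier", positive = TRUE)
  county_emissions |>
    filter(.data$period == anchor_period) |>
    summarise(tons = sum(.data$tons) * multiplier,
      .by = c("county_id", "pollutant", "height_bin")
    )
}
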
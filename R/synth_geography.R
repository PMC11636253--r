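# Synthetic county geography: a planar km domain tiled into contiguous
# regions of equal-area counties. Only inter-centroid distances matter to the
# downstream physics, so a flat synthetic domain sidesteps projection
# ambiguity entirely.

#' Generate a synthetic county geography
#'
#' Tiles a square planar domain into `n_regions` contiguous vertical strips
#' (the regions) and slices each strip into `counties_per_region` equal-area
#' counties. Each county gets a geometric centroid and a population-weighted
#' centroid jittered away from it; the population-weighted centroid is the
#' receptor (and release point) used by the atmospheric model.
#'
#' @param n_regions Number of regions (the study design uses 9).
#' @param counties_per_region Counties per region.
#' @param domain_size Side length of the square domain, km.
#' @param seed Integer seed; identical seeds give byte-identical output.
#'
#' @return A tibble with one row per county: `county_id`, `region_id`,
#'   `cx`, `cy` (geometric centroid, km), `area` (km^2), `pw_x`, `pw_y`
#'   (population-weighted centroid, km).
#' @export
#' @examples
#' gen_counties(3, 4, 300, seed = 1)
gen_counties <- function(n_regions, counties_per_region, domain_size, seed) {
  check_scalar_number(n_regions, "n_regions", positive = TRUE, integerish = TRUE)
  check_scalar_number(counties_per_region, "counties_per_region",
    positive = TRUE, integerish = TRUE
  )
  check_scalar_number(domain_size, "domain_size", positive = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)

  n_regions <- as.integer(n_regions)
  counties_per_region <- as.integer(counties_per_region)
  strip_w <- domain_size / n_regions
  cell_h <- domain_size / counties_per_region

  grid <- tidyr::expand_grid(
    region_id = seq_len(n_regions),
    slot = seq_len(counties_per_region)
  )

  withr::with_seed(seed, {
    jx <- runif(nrow(grid), -0.2, 0.2) * strip_w
    jy <- runif(nrow(grid), -0.2, 0.2) * cell_h
  })

  grid |>
    mutate(
      county_id = sprintf("C%03d", dplyr::row_number()),
      cx = (.data$region_id - 0.5) * strip_w,
      cy = (.data$slot - 0.5) * cell_h,
      area = strip_w * cell_h,
      pw_x = .data$cx + jx,
      pw_y = .data$cy + jy
    ) |>
    select("county_id", "region_id", "cx", "cy", "area", "pw_x", "pw_y")
}

#' Write counties as a GeoJSON FeatureCollection
#'
#' Emits point features at the geometric centroid with the county attributes
#' (including the population-weighted centroid) as properties. Coordinates are
#' planar km, recorded as such in the collection's `crs_note`.
#'
#' @param counties County tibble from [gen_counties()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counties_geojson <- function(counties, path) {
  check_columns(counties, c("county_id", "region_id", "cx", "cy", "area", "pw_x", "pw_y"),
    name = "counties"
  )
  features <- purrr::pmap(counties, function(county_id, region_id, cx, cy, area, pw_x, pw_y) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(cx, cy)),
      properties = list(
        county_id = county_id, region_id = region_id, area = area,
        pw_x = pw_x, pw_y = pw_y
      )
    )
  })
  fc <- list(
    type = "FeatureCollection",
    crs_note = "planar kilometres (synthetic domain)",
    features = features
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read counties from a GeoJSON FeatureCollection
#'
#' Inverse of [write_counties_geojson()]. Polygon geometry is optional; only
#' the centroid properties are required.
#'
#' @param path GeoJSON file path.
#' @return County tibble in the [gen_counties()] layout.
#' @export
read_counties_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$features)) abort_structural("Not a GeoJSON FeatureCollection.")
  purrr::map_dfr(fc$features, function(f) {
    p <- f$properties
    tibble(
      county_id = p$county_id,
      region_id = as.integer(p$region_id),
      cx = as.numeric(f$geometry$coordinates[[1]]),
      cy = as.numeric(f$geometry$coordinates[[2]]),
      area = as.numeric(p$area),
      pw_x = as.numeric(p$pw_x),
      pw_y = as.numeric(p$pw_y)
    )
  })
}
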
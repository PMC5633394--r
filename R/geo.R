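# Geographic cohort construction: great-circle distances, the parental
# birthplace filter, mean-of-parents coordinates and uniform grid subsampling.

# Mean Earth radius in km; all distances are spherical (haversine).
EARTH_RADIUS_KM <- 6371

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km (mean Earth radius).
#' All arguments are decimal degrees and are recycled to a common length,
#' so the function is vectorised over point pairs.
#'
#' @param lat1,lon1 Coordinates of the first point (decimal degrees).
#' @param lat2,lon2 Coordinates of the second point (decimal degrees).
#' @return Numeric vector of distances in km.
#' @examples
#' # Helsinki to Oulu, about 540 km
#' great_circle_km(60.1708, 24.9375, 65.0142, 25.4719)
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  validate_coords(lat1, lon1)
  validate_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

validate_coords <- function(lat, lon) {
  bad_lat <- !is.na(lat) & (lat < -90 | lat > 90)
  bad_lon <- !is.na(lon) & (lon <= -180 | lon > 180)
  if (any(bad_lat)) abort("latitude out of range [-90, 90].")
  if (any(bad_lon)) abort("longitude out of range (-180, 180].")
  invisible(NULL)
}

#' Derive individual coordinates as the mean of the parents' coordinates
#'
#' Adds (or overwrites) `latitude` and `longitude` columns as the
#' coordinate-wise arithmetic mean of the parental birthplaces.
#'
#' @param records A data frame with columns `father_lat`, `father_lon`,
#'   `mother_lat`, `mother_lon`.
#' @return The input as a tibble with `latitude` and `longitude` columns.
#' @export
add_mean_parent_coords <- function(records) {
  tibble::as_tibble(records) |>
    dplyr::mutate(
      latitude = (.data$father_lat + .data$mother_lat) / 2,
      longitude = (.data$father_lon + .data$mother_lon) / 2
    )
}

#' Filter individuals by the distance between their parents' birthplaces
#'
#' Retains individuals whose parents were born within `max_km` of each
#' other (great-circle distance, boundary inclusive).  Records with a
#' missing parental coordinate are dropped and their count reported via
#' a message and the `n_missing` attribute.
#'
#' @param records A data frame with columns `father_lat`, `father_lon`,
#'   `mother_lat`, `mother_lon` (one row per individual).
#' @param max_km Maximum parent-to-parent distance in km. Default 80.
#' @return A tibble: the retained subset, in the original order, with a
#'   `parent_km` column added. Attributes `n_missing` and `n_filtered`
#'   record the counts dropped.
#' @export
parental_distance_filter <- function(records, max_km = 80) {
  check_number(max_km, "max_km", lower = 0)
  records <- tibble::as_tibble(records)
  coords <- c("father_lat", "father_lon", "mother_lat", "mother_lon")
  if (!all(coords %in% names(records))) {
    abort("`records` must have father_lat/father_lon/mother_lat/mother_lon.")
  }
  complete <- stats::complete.cases(records[coords])
  n_missing <- sum(!complete)
  if (n_missing > 0L) {
    inform(sprintf("%d record(s) with missing parental coordinates excluded.",
                   n_missing))
  }
  kept <- records[complete, , drop = FALSE]
  kept$parent_km <- great_circle_km(kept$father_lat, kept$father_lon,
                                    kept$mother_lat, kept$mother_lon)
  out <- dplyr::filter(kept, .data$parent_km <= max_km)
  attr(out, "n_missing") <- n_missing
  attr(out, "n_filtered") <- nrow(kept) - nrow(out)
  out
}

# Local planar projection (km): x along longitude scaled by cos of the
# cohort's mean latitude, y along latitude. Distortion over a country-
# sized extent at high latitudes is well under the 25 km cell size.
project_local_km <- function(lat, lon, lat0 = mean(lat)) {
  list(
    x = EARTH_RADIUS_KM * (lon * pi / 180) * cos(lat0 * pi / 180),
    y = EARTH_RADIUS_KM * (lat * pi / 180)
  )
}

#' Spatially uniform subsampling on a square grid
#'
#' Lays a planar grid of `cell_km` x `cell_km` cells over the cohort
#' (local equirectangular projection centred on the cohort's mean
#' latitude, anchored at the bounding-box minimum) and keeps at most
#' `max_per_cell` individuals per cell, drawn uniformly without
#' replacement where a cell holds more.
#'
#' @param records A data frame with `latitude` and `longitude` columns
#'   (see [add_mean_parent_coords()]).
#' @param cell_km Grid cell side in km. Default 25.
#' @param max_per_cell Maximum individuals retained per cell.
#' @param seed Integer seed making the within-cell draws reproducible.
#' @return A tibble: the retained subset, in the original row order.
#' @export
grid_subsample <- function(records, cell_km = 25, max_per_cell, seed = NULL) {
  check_number(cell_km, "cell_km", lower = 1e-9)
  check_number(max_per_cell, "max_per_cell", lower = 1)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    return(records)
  }
  if (!all(c("latitude", "longitude") %in% names(records))) {
    abort("`records` must have `latitude` and `longitude` columns.")
  }
  p <- project_local_km(records$latitude, records$longitude)
  cell <- paste(floor((p$x - min(p$x)) / cell_km),
                floor((p$y - min(p$y)) / cell_km))
  keep <- with_seed_or_current(seed, {
    idx <- split(seq_len(nrow(records)), cell)
    unlist(lapply(idx, function(i) {
      if (length(i) <= max_per_cell) i else sample(i, max_per_cell)
    }), use.names = FALSE)
  })
  records[sort(keep), , drop = FALSE]
}
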
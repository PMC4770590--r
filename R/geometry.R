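# Local azimuthal-equidistant projection about the colony.
#
# Points at most ~25 km from a central place are projected to planar (x, y)
# kilometres east/north of the colony by pairing the great-circle distance
# with the initial bearing; the inverse is the spherical destination-point
# formula. On a sphere these are exact inverses, so round-trip error is
# limited only by floating point. A consistent mean Earth radius of 6371 km
# is used throughout.

.earth_radius_m <- 6371000

#' Project longitude/latitude to colony-centred planar kilometres
#'
#' Azimuthal-equidistant projection about a central place (the breeding
#' colony). `x` points east, `y` north, both in kilometres.
#'
#' @param lat,lon Numeric vectors of coordinates in decimal degrees.
#' @param colony_lat,colony_lon Colony coordinates in decimal degrees.
#' @return A tibble with columns `x_km` and `y_km`.
#' @seealso [planar_to_lonlat()] for the inverse.
#' @export
lonlat_to_planar <- function(lat, lon, colony_lat, colony_lon) {
  colony <- cbind(colony_lon, colony_lat)
  p <- cbind(lon, lat)
  d <- geosphere::distHaversine(colony, p, r = .earth_radius_m) / 1000
  b <- geosphere::bearing(colony, p, a = .earth_radius_m, f = 0)
  b[is.na(b)] <- 0 # bearing undefined at the colony itself; distance is 0
  rad <- b * pi / 180
  tibble(x_km = d * sin(rad), y_km = d * cos(rad))
}

#' Invert the colony-centred projection
#'
#' @param x_km,y_km Planar coordinates in kilometres east/north of the colony.
#' @inheritParams lonlat_to_planar
#' @return A tibble with columns `lat_dd` and `lon_dd`.
#' @export
planar_to_lonlat <- function(x_km, y_km, colony_lat, colony_lon) {
  d <- sqrt(x_km^2 + y_km^2) * 1000
  b <- atan2(x_km, y_km) * 180 / pi
  p <- geosphere::destPoint(cbind(colony_lon, colony_lat), b, d,
    r = .earth_radius_m
  )
  tibble(lat_dd = p[, "lat"], lon_dd = p[, "lon"])
}

#' Great-circle distance from the colony
#'
#' Haversine distance in kilometres, the scale on which foraging ranges and
#' capture distances are reported.
#'
#' @inheritParams lonlat_to_planar
#' @return Numeric vector of distances in km.
#' @export
colony_distance <- function(lat, lon, colony_lat, colony_lon) {
  geosphere::distHaversine(
    cbind(colony_lon, colony_lat), cbind(lon, lat),
    r = .earth_radius_m
  ) / 1000
}
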
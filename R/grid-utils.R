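#' Cell area from latitude
#'
#' Area in hectares of a regular lat-lon grid cell centred at `lat`, using a
#' spherical Earth (meridian degree = 111.195 km). Area shrinks with the
#' cosine of latitude.
#'
#' @param lat latitude in degrees
#' @param resolution_deg cell edge length in degrees (default 0.5)
#' @return area in ha, same length as `lat`
#' @export
cell_area_ha <- function(lat, resolution_deg = 0.5) {
  stopifnot(all(abs(lat) < 90))
  km_per_deg <- 111.195
  area_km2 <- (km_per_deg * resolution_deg)^2 * cos(lat * pi / 180)
  area_km2 * 100
}

#' Expand a growing season to month indices
#'
#' Seasons are stored compactly as a start month and a length; they wrap
#' around the year end.
#'
#' @param start first month of the season (1..12)
#' @param len season length in months (1..12)
#' @return integer vector of month indices in 1..12
#' @export
season_months <- function(start, len) {
  stopifnot(length(start) == 1, length(len) == 1,
            start >= 1, start <= 12, len >= 1, len <= 12)
  ((as.integer(start) - 1L + seq_len(len) - 1L) %% 12L) + 1L
}

#' Great-circle distance between cell centres
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorised)
#' @return distance in km
#' @export
greatcircle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}
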
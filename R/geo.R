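#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorised over coordinates.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0) # ~111.195 km, one degree of latitude
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90, na.rm = TRUE),
            all(abs(c(lon1, lon2)) <= 180, na.rm = TRUE))
  r <- 6371.0088
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dp <- p2 - p1
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * r * asin(sqrt(a))
}

.EARTH_R_KM <- 6371.0088

#' Project lon/lat to a local azimuthal-equidistant plane
#'
#' Forward azimuthal-equidistant projection about `centre`, returning planar
#' coordinates in km. Distances and azimuths from the centre are preserved
#' exactly, which keeps home-range-scale geometry Euclidean.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param centre Numeric length-2 `c(lon, lat)` of the projection centre.
#' @return A two-column matrix (x, y) in km.
#' @seealso [unproject_aeqd()]
#' @export
project_aeqd <- function(lon, lat, centre) {
  lam0 <- centre[1] * pi / 180; phi0 <- centre[2] * pi / 180
  lam <- lon * pi / 180; phi <- lat * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(pmax(cosc, -1), 1)
  c_ang <- acos(cosc)
  # k = c / sin(c), with limit 1 at c = 0
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- .EARTH_R_KM * k * cos(phi) * sin(lam - lam0)
  y <- .EARTH_R_KM * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x = x, y = y)
}

#' Inverse azimuthal-equidistant projection
#'
#' @param xy Two-column matrix (x, y) in km.
#' @inheritParams project_aeqd
#' @return A two-column matrix (lon, lat) in decimal degrees.
#' @export
unproject_aeqd <- function(xy, centre) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  lam0 <- centre[1] * pi / 180; phi0 <- centre[2] * pi / 180
  rho <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  c_ang <- rho / .EARTH_R_KM
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cosc * sin(phi0) + xy[, 2] * sinc * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(xy[, 1] * sinc,
                             rho * cos(phi0) * cosc - xy[, 2] * sin(phi0) * sinc))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Southern-hemisphere season of a calendar month
#'
#' Dec-Feb is summer, Mar-May autumn, Jun-Aug winter, Sep-Nov spring.
#'
#' @param month Integer month(s) in 1..12.
#' @return Character vector of `"summer"`, `"autumn"`, `"winter"`, `"spring"`.
#' @export
season_of <- function(month) {
  if (any(is.na(month)) || any(month < 1 | month > 12) || any(month != floor(month)))
    stop("month must be an integer in 1..12")
  c("summer", "summer", "autumn", "autumn", "autumn",
    "winter", "winter", "winter", "spring", "spring", "spring",
    "summer")[month]
}
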
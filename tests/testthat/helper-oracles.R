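# Independent oracles and small fixture builders shared across test files.
# Oracles deliberately avoid the package's own code paths.

# spherical law of cosines distance (independent of the haversine path)
slc_km <- function(lon1, lat1, lon2, lat2, R = 6371.0088) {
  to <- pi / 180
  d <- sin(lat1 * to) * sin(lat2 * to) +
    cos(lat1 * to) * cos(lat2 * to) * cos((lon2 - lon1) * to)
  R * acos(pmin(pmax(d, -1), 1))
}

# build a minimal track data.frame from hour offsets and planar km offsets
# (small-angle conversion about a reference point; adequate at test scales)
make_track <- function(hours, x_km = 0, y_km = 0, bird_id = "t1",
                       lon0 = 145, lat0 = -35, utc_offset_h = 0,
                       start = as.POSIXct("2021-01-01 00:00:00", tz = "UTC"),
                       species = "SNI", age_class = "adult") {
  n <- length(hours)
  deg_km <- pi / 180 * 6371.0088   # km per degree of great circle
  lat <- lat0 + rep_len(y_km, n) / deg_km
  lon <- lon0 + rep_len(x_km, n) / (deg_km * cos(lat0 * pi / 180))
  data.frame(bird_id = bird_id, species = species, age_class = age_class,
             timestamp = start + hours * 3600, lon = lon, lat = lat,
             utc_offset_h = utc_offset_h, stringsAsFactors = FALSE)
}

# brute-force visit scan: maximal runs of inside-fixes, no gap merging
brute_force_visits <- function(track, polygon) {
  inside <- point_in_polygon(track$lon, track$lat, polygon)
  out <- list()
  i <- 1
  while (i <= length(inside)) {
    if (inside[i]) {
      j <- i
      while (j < length(inside) && inside[j + 1]) j <- j + 1
      out[[length(out) + 1]] <- c(start = i, end = j)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# exhaustive enumeration of two-group splits for the permutation oracle
enumerate_split_fraction <- function(pool, na, stat, obs) {
  combs <- utils::combn(length(pool), na)
  hits <- apply(combs, 2, function(idx)
    abs(stat(pool[idx]) - stat(pool[-idx])) >= abs(obs) - 1e-12)
  mean(hits)
}

# unit square polygon (counter-clockwise ring), lon/lat degrees
square_poly <- function(lon0, lat0, half = 0.5) {
  cbind(lon = c(lon0 - half, lon0 + half, lon0 + half, lon0 - half),
        lat = c(lat0 - half, lat0 - half, lat0 + half, lat0 + half))
}

# two consecutive resident months, second displaced by `shift_km` east
# (teleport at the month boundary); timestamps continuous on a 6-h grid
two_site_track <- function(shift_km, seed = 1, sigma2 = 100) {
  t1 <- simulate_ouf_track(sim_config(sigma2, 24, 1, 6, 30,
                                      centre = c(145, -35), seed = seed,
                                      start = as.POSIXct("2021-01-01", tz = "UTC")))
  t2 <- simulate_ouf_track(sim_config(sigma2, 24, 1, 6, 27,
                                      centre = c(145, -35), seed = seed + 1000,
                                      start = as.POSIXct("2021-02-01", tz = "UTC")))
  xy2 <- project_aeqd(t2$lon, t2$lat, c(145, -35))
  ll2 <- unproject_aeqd(cbind(xy2[, 1] + shift_km, xy2[, 2]), c(145, -35))
  t2$lon <- ll2[, 1]; t2$lat <- ll2[, 2]
  trk <- rbind(t1[t1$timestamp < as.POSIXct("2021-02-01", tz = "UTC"), ], t2)
  trk$bird_id <- "b2site"
  trk
}
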
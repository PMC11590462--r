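# Site-revisitation statistics: visits of tracks to residency-area polygons,
# per-area / per-bird summaries, and classification of areas against supplied
# wetland and breeding-site layers.
#
# A polygon here is a two-column lon/lat matrix (one ring, implicitly closed)
# or a list of such rings (multipolygon; holes are not modelled). Boundary
# points count as inside (closed-set convention).

.as_rings <- function(polygon) {
  if (is.matrix(polygon)) list(polygon) else polygon
}

#' Point-in-polygon test (ray casting, boundary-inclusive)
#'
#' @param lon,lat Point coordinates (vectorised).
#' @param polygon A ring matrix or list of ring matrices.
#' @param eps Snap tolerance (degrees) for the on-boundary test.
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, polygon, eps = 1e-9) {
  rings <- .as_rings(polygon)
  inside <- rep(FALSE, length(lon))
  for (ring in rings) {
    rx <- ring[, 1]; ry <- ring[, 2]
    n <- length(rx)
    if (rx[1] == rx[n] && ry[1] == ry[n]) { rx <- rx[-n]; ry <- ry[-n]; n <- n - 1 }
    cross <- rep(FALSE, length(lon))
    onb <- rep(FALSE, length(lon))
    j <- n
    for (i in seq_len(n)) {
      xi <- rx[i]; yi <- ry[i]; xj <- rx[j]; yj <- ry[j]
      # on-segment check
      dx <- xj - xi; dy <- yj - yi
      len2 <- dx * dx + dy * dy
      if (len2 > 0) {
        t <- pmin(pmax(((lon - xi) * dx + (lat - yi) * dy) / len2, 0), 1)
        d2 <- (lon - (xi + t * dx))^2 + (lat - (yi + t * dy))^2
        onb <- onb | d2 <= eps^2
      } else {
        onb <- onb | ((lon - xi)^2 + (lat - yi)^2 <= eps^2)
      }
      hit <- ((yi > lat) != (yj > lat)) &
        (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
      cross <- xor(cross, hit & !is.na(hit))
      j <- i
    }
    inside <- inside | cross | onb
  }
  inside
}

.validate_polygon <- function(polygon) {
  rings <- .as_rings(polygon)
  for (ring in rings) {
    if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3)
      stop("invalid polygon: each ring needs a 2-column matrix with >= 3 vertices")
    if (any(!is.finite(ring))) stop("invalid polygon: non-finite vertex")
  }
  invisible(polygon)
}

#' Detect visits of a track to a site polygon
#'
#' Point-in-polygon is evaluated per fix; maximal runs of inside-fixes form
#' visits, and an excursion outside shorter than `min_gap_h` does not split a
#' visit. The excursion duration is estimated as the time between the two
#' inside runs minus one nominal fix interval (the track's median interval),
#' floored at zero, so a single outside fix at 6-h sampling counts as a 6-h
#' excursion. With `min_gap_h = 0` no merging ever occurs. Arrival and
#' departure are the first and last inside-fix times (no interpolation of
#' boundary crossings).
#'
#' @param track A track data.frame.
#' @param polygon Ring matrix or list of rings (lon/lat).
#' @param min_gap_h Minimum outside gap (hours) that separates two visits;
#'   default 12.
#' @param area_id Identifier recorded on the visits.
#' @return `data.frame(bird_id, area_id, arrival, departure, duration_days,
#'   gap_to_next_visit_days, n_fixes)`, zero rows if never inside.
#' @export
detect_visits <- function(track, polygon, min_gap_h = 12, area_id = "area1") {
  .validate_track(track)
  .validate_polygon(polygon)
  inside <- point_in_polygon(track$lon, track$lat, polygon)
  if (!any(inside)) {
    return(data.frame(bird_id = character(), area_id = character(),
                      arrival = as.POSIXct(character(), tz = "UTC"),
                      departure = as.POSIXct(character(), tz = "UTC"),
                      duration_days = numeric(),
                      gap_to_next_visit_days = numeric(),
                      n_fixes = integer(), stringsAsFactors = FALSE))
  }
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by a short outside excursion
  med_int_h <- stats::median(as.numeric(diff(track$timestamp), units = "hours"))
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    gap_h <- as.numeric(difftime(track$timestamp[runs$start[i]],
                                 track$timestamp[merged$end[nrow(merged)]],
                                 units = "hours"))
    excursion_h <- max(gap_h - med_int_h, 0)
    if (excursion_h < min_gap_h) merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  arrival <- track$timestamp[merged$start]
  departure <- track$timestamp[merged$end]
  dur <- as.numeric(difftime(departure, arrival, units = "days"))
  gap <- c(as.numeric(difftime(arrival[-1], departure[-nrow(merged)],
                               units = "days")), NA_real_)
  nfx <- vapply(seq_len(nrow(merged)), function(i)
    sum(inside[merged$start[i]:merged$end[i]]), 0L)
  data.frame(bird_id = track$bird_id[1], area_id = area_id, arrival = arrival,
             departure = departure, duration_days = dur,
             gap_to_next_visit_days = gap, n_fixes = nfx,
             stringsAsFactors = FALSE)
}

#' Summarise visits across birds and areas
#'
#' @param visits A visits data.frame ([detect_visits()] rows combined across
#'   birds and areas).
#' @return A list: `per_area` (`area_id`, `n_birds`, `n_visits`,
#'   `multi_bird`), `per_bird` (`bird_id`, `n_areas`, `n_visits`, visit
#'   duration and between-visit-gap median/mean/sd/min/max), and `monthly`
#'   (arrival and departure counts per area and calendar month).
#' @export
revisit_summary <- function(visits) {
  if (nrow(visits) == 0)
    return(list(per_area = data.frame(), per_bird = data.frame(),
                monthly = data.frame()))
  per_area <- do.call(rbind, lapply(split(visits, visits$area_id), function(v)
    data.frame(area_id = v$area_id[1], n_birds = length(unique(v$bird_id)),
               n_visits = nrow(v), multi_bird = length(unique(v$bird_id)) > 1,
               stringsAsFactors = FALSE)))
  stat5 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(median = NA, mean = NA, sd = NA, min = NA, max = NA))
    c(median = stats::median(x), mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      min = min(x), max = max(x))
  }
  per_bird <- do.call(rbind, lapply(split(visits, visits$bird_id), function(v) {
    dur <- stat5(v$duration_days); gp <- stat5(v$gap_to_next_visit_days)
    data.frame(bird_id = v$bird_id[1], n_areas = length(unique(v$area_id)),
               n_visits = nrow(v),
               dur_median = dur["median"], dur_mean = dur["mean"],
               dur_sd = dur["sd"], dur_min = dur["min"], dur_max = dur["max"],
               gap_median = gp["median"], gap_mean = gp["mean"],
               gap_sd = gp["sd"], gap_min = gp["min"], gap_max = gp["max"],
               stringsAsFactors = FALSE)
  }))
  monthly <- stats::aggregate(
    list(n_arrivals = rep(1, nrow(visits))),
    list(area_id = visits$area_id,
         month = as.integer(format(visits$arrival, "%m"))), sum)
  dep <- stats::aggregate(
    list(n_departures = rep(1, nrow(visits))),
    list(area_id = visits$area_id,
         month = as.integer(format(visits$departure, "%m"))), sum)
  monthly <- merge(monthly, dep, by = c("area_id", "month"), all = TRUE)
  monthly[is.na(monthly)] <- 0
  rownames(per_area) <- rownames(per_bird) <- NULL
  list(per_area = per_area, per_bird = per_bird, monthly = monthly)
}

# segment intersection test (inclusive of endpoints/collinear touching)
.segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < 1e-15) 0 else sign(v)
  }
  on_seg <- function(a, b, c)
    min(a[1], b[1]) - 1e-15 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-15 &&
    min(a[2], b[2]) - 1e-15 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-15
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
    (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
}

#' Do two polygons intersect?
#'
#' Closed-set convention: shared boundary points count as intersection.
#' True iff a vertex of one lies in the other or any pair of edges crosses.
#'
#' @param a,b Ring matrices or lists of rings (lon/lat).
#' @return Logical scalar.
#' @export
polygons_intersect <- function(a, b) {
  ra <- .as_rings(a); rb <- .as_rings(b)
  for (r1 in ra) if (any(point_in_polygon(r1[, 1], r1[, 2], b))) return(TRUE)
  for (r2 in rb) if (any(point_in_polygon(r2[, 1], r2[, 2], a))) return(TRUE)
  close_ring <- function(r) if (all(r[1, ] == r[nrow(r), ])) r else rbind(r, r[1, ])
  for (r1 in lapply(ra, close_ring)) for (r2 in lapply(rb, close_ring)) {
    for (i in seq_len(nrow(r1) - 1)) for (j in seq_len(nrow(r2) - 1)) {
      if (.segments_intersect(r1[i, ], r1[i + 1, ], r2[j, ], r2[j + 1, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Classify residency areas against wetland / breeding-site layers
#'
#' A flag is `TRUE` iff the residency polygon has a non-empty geometric
#' intersection with any polygon of the layer; a missing layer gives `NA`
#' (unknown), never `FALSE`. Layer order is irrelevant.
#'
#' @param areas Named list of residency polygons (ring matrices or ring
#'   lists, WGS84 lon/lat).
#' @param layers Named list of layers; each layer is a list of polygons, e.g.
#'   from [read_geojson_polygons()]. Conventional names: `ramsar`, `diwa`,
#'   `managed_floodplain`, `breeding_sites`, `basin_boundary`.
#' @return A `data.frame` with `area_id` and one logical column per
#'   conventional layer (`ramsar`, `diwa_listed`, `managed_floodplain`,
#'   `known_breeding_site`, `basin_member`), plus any extra supplied layers.
#' @export
classify_areas <- function(areas, layers) {
  if (is.null(names(areas))) names(areas) <- paste0("area", seq_along(areas))
  std <- c(ramsar = "ramsar", diwa_listed = "diwa",
           managed_floodplain = "managed_floodplain",
           known_breeding_site = "breeding_sites",
           basin_member = "basin_boundary")
  extra <- setdiff(names(layers), std)
  flag <- function(area, layer_name) {
    if (!layer_name %in% names(layers)) return(NA)
    any(vapply(layers[[layer_name]], function(p) polygons_intersect(area, p), TRUE))
  }
  out <- do.call(rbind, lapply(names(areas), function(id) {
    row <- data.frame(area_id = id, stringsAsFactors = FALSE)
    for (col in names(std)) row[[col]] <- flag(areas[[id]], std[[col]])
    for (col in extra) row[[col]] <- flag(areas[[id]], col)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Group residency polygons that mutually overlap
#'
#' Union-find over pairwise-intersecting polygons: the declared rule for
#' counting distinct residency areas shared across birds.
#'
#' @param polys Named list of polygons.
#' @return Integer vector of group ids aligned with `polys`.
#' @export
group_overlapping_areas <- function(polys) {
  n <- length(polys)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1, 0))) for (j in seq(i + 1, n)) {
    if (polygons_intersect(polys[[i]], polys[[j]])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}
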
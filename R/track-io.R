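# Reading, filtering, regularizing and segmenting telemetry fixes.
# A "track" throughout the package is a plain data.frame with columns
# bird_id, species, age_class, timestamp (POSIXct UTC), lon, lat, utc_offset_h,
# chronologically ordered within bird, no duplicate timestamps.

.TRACK_COLS <- c("bird_id", "species", "age_class", "timestamp", "lon", "lat",
                 "utc_offset_h")

# per-element ISO-ish timestamp parsing; unparseable entries become NA
.parse_times <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
            "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (f in fmts) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], f, tz = "UTC"))
  }
  out
}

.validate_track <- function(track) {
  stopifnot(is.data.frame(track), all(c("bird_id", "timestamp", "lon", "lat")
                                      %in% names(track)))
  if (length(unique(track$bird_id)) > 1) stop("track must contain a single bird")
  if (is.unsorted(as.numeric(track$timestamp), strictly = TRUE))
    stop("track timestamps must be strictly increasing")
  invisible(track)
}

#' Read GPS fixes from CSV into per-bird tracks
#'
#' Accepts the package's standard dialect
#' (`bird_id,species,age_class,timestamp,lon,lat[,utc_offset_h]`) or Movebank
#' exports (`individual-local-identifier,timestamp,location-long,location-lat`).
#' Rows with unparseable timestamps or out-of-range coordinates are dropped
#' with a message; duplicate timestamps within a bird are dropped with a
#' warning (first kept).
#'
#' @param path CSV file path.
#' @param dialect `"standard"` or `"movebank"`.
#' @param col_map Optional named character vector overriding column names,
#'   e.g. `c(bird_id = "id", timestamp = "time", lon = "x", lat = "y")`.
#' @param default_utc_offset_h Used when the file has no offset column.
#' @return A named list of track data.frames, one per bird (empty list for an
#'   empty file).
#' @export
read_fixes <- function(path, dialect = c("standard", "movebank"), col_map = NULL,
                       default_utc_offset_h = 0) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) return(list())
  map <- switch(dialect,
    standard = c(bird_id = "bird_id", species = "species",
                 age_class = "age_class", timestamp = "timestamp",
                 lon = "lon", lat = "lat", utc_offset_h = "utc_offset_h"),
    movebank = c(bird_id = "individual-local-identifier",
                 species = "individual-taxon-canonical-name",
                 age_class = "age_class", timestamp = "timestamp",
                 lon = "location-long", lat = "location-lat",
                 utc_offset_h = "utc_offset_h"))
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  for (need in c("bird_id", "timestamp", "lon", "lat"))
    if (!map[[need]] %in% names(raw))
      stop(sprintf("missing mandatory column '%s'", map[[need]]))
  get <- function(field, default) {
    if (map[[field]] %in% names(raw)) raw[[map[[field]]]] else default
  }
  df <- data.frame(
    bird_id = as.character(raw[[map[["bird_id"]]]]),
    species = as.character(get("species", "other")),
    age_class = as.character(get("age_class", "adult")),
    timestamp = .parse_times(as.character(raw[[map[["timestamp"]]]])),
    lon = suppressWarnings(as.numeric(raw[[map[["lon"]]]])),
    lat = suppressWarnings(as.numeric(raw[[map[["lat"]]]])),
    utc_offset_h = as.numeric(get("utc_offset_h", default_utc_offset_h)),
    stringsAsFactors = FALSE)
  bad <- is.na(df$timestamp) | is.na(df$lon) | is.na(df$lat) |
    abs(df$lon) > 180 | abs(df$lat) > 90
  if (any(bad))
    message(sum(bad), " row(s) dropped: unparseable timestamp or invalid coordinates")
  df <- df[!bad, , drop = FALSE]
  out <- lapply(split(df, df$bird_id), function(b) {
    b <- b[order(b$timestamp), , drop = FALSE]
    dup <- duplicated(b$timestamp)
    if (any(dup))
      warning(sprintf("bird %s: %d duplicate timestamp(s) dropped",
                      b$bird_id[1], sum(dup)))
    rownames(b) <- NULL
    b[!dup, , drop = FALSE]
  })
  out[order(names(out))]
}

#' Filter tracks by exclusion windows and minimum tracking span
#'
#' Removes fixes inside any per-bird exclusion window (nesting or
#' pre-dispersal periods, supplied from field knowledge), then drops birds
#' whose remaining first-to-last span is below `min_days`.
#'
#' @param tracks List of track data.frames.
#' @param min_days Minimum retained span in days (default 30: birds tracked
#'   for < 30 days are removed).
#' @param exclusion_windows Named list (by bird id) of data.frames with
#'   `start`, `end` (Dates or coercible); fixes with `start <= date <= end`
#'   are removed.
#' @return Filtered list of tracks.
#' @export
filter_tracks <- function(tracks, min_days = 30, exclusion_windows = NULL) {
  out <- lapply(tracks, function(trk) {
    win <- exclusion_windows[[trk$bird_id[1]]]
    if (!is.null(win) && nrow(win) > 0) {
      d <- as.Date(format(trk$timestamp, "%Y-%m-%d"))
      drop <- rep(FALSE, nrow(trk))
      for (i in seq_len(nrow(win)))
        drop <- drop | (d >= as.Date(win$start[i]) & d <= as.Date(win$end[i]))
      trk <- trk[!drop, , drop = FALSE]
    }
    trk
  })
  keep <- vapply(out, function(trk) {
    nrow(trk) >= 2 &&
      as.numeric(difftime(max(trk$timestamp), min(trk$timestamp), units = "days")) >= min_days
  }, TRUE)
  out[keep]
}

#' Place a track on a common regular grid
#'
#' Grid times are anchored at UTC midnight (00:00, 06:00, 12:00, 18:00 for the
#' default 6-h interval). Each slot receives the nearest raw fix within
#' `tolerance_min`; otherwise the slot is left missing (`NA` coordinates).
#' Positions are never interpolated. A fix can fill at most one slot; a fix
#' exactly midway between two slots goes to the earlier slot, and when two
#' fixes compete for a slot the nearer (then earlier) wins.
#'
#' @param track A track data.frame.
#' @param grid_interval_h Grid step in hours (> 0), default 6.
#' @param tolerance_min Assignment tolerance in minutes, default 90.
#' @return A `data.frame` with one row per grid slot: `timestamp`, `lon`,
#'   `lat`, `observed`, plus the bird metadata columns; attributes
#'   `grid_interval_h` and `utc_offset_h` are set. Class `"regular_track"`.
#' @export
regularize <- function(track, grid_interval_h = 6, tolerance_min = 90) {
  if (grid_interval_h <= 0) stop("grid_interval_h must be > 0")
  if ("observed" %in% names(track))    # re-regularizing: use real fixes only
    track <- track[track$observed, setdiff(names(track), "observed"), drop = FALSE]
  .validate_track(track)
  step <- grid_interval_h * 3600
  t_num <- as.numeric(track$timestamp)
  g0 <- floor(min(t_num) / 86400) * 86400          # UTC midnight anchor
  first <- g0 + floor((min(t_num) - g0) / step) * step
  last <- g0 + ceiling((max(t_num) - g0) / step) * step
  grid <- seq(first, last, by = step)
  # nearest slot per fix; ties (exact midpoint) to the earlier slot
  lo <- g0 + floor((t_num - g0) / step) * step
  hi <- lo + step
  slot <- ifelse(t_num - lo <= hi - t_num, lo, hi)
  dist <- abs(t_num - slot)
  ok <- dist <= tolerance_min * 60
  assign <- rep(NA_integer_, length(grid))
  idx <- which(ok)
  idx <- idx[order(dist[idx], t_num[idx])]         # nearer, then earlier, wins
  for (i in idx) {
    k <- match(slot[i], grid)
    if (!is.na(k) && is.na(assign[k])) assign[k] <- i
  }
  # trim unobserved slots at the edges: the grid spans the observed range
  if (all(is.na(assign)))
    stop("no fix falls within tolerance of any grid slot")
  obs_rng <- range(which(!is.na(assign)))
  keep <- seq(obs_rng[1], obs_rng[2])
  grid <- grid[keep]; assign <- assign[keep]
  out <- data.frame(
    bird_id = track$bird_id[1],
    species = track$species[1] %||% "other",
    age_class = track$age_class[1] %||% "adult",
    timestamp = as.POSIXct(grid, tz = "UTC", origin = "1970-01-01"),
    lon = ifelse(is.na(assign), NA_real_, track$lon[assign]),
    lat = ifelse(is.na(assign), NA_real_, track$lat[assign]),
    observed = !is.na(assign),
    stringsAsFactors = FALSE)
  attr(out, "grid_interval_h") <- grid_interval_h
  attr(out, "utc_offset_h") <- track$utc_offset_h[1] %||% 0
  class(out) <- c("regular_track", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a regular track into calendar-month segments
#'
#' Month membership is judged in local time (`timestamp + utc_offset_h`):
#' seasons and midnights are biologically local. Only months with at least one
#' observed fix are returned.
#'
#' @param rtrack A [regularize()]d track.
#' @return A list of `month_segment` objects: each is the regular-track slice
#'   for one local calendar month with attributes `year`, `month`, `n_fixes`
#'   (observed count) and `window_h` (calendar-month span in hours).
#' @export
split_months <- function(rtrack) {
  stopifnot(inherits(rtrack, "regular_track"))
  if (nrow(rtrack) == 0 || !any(rtrack$observed)) return(list())
  off <- attr(rtrack, "utc_offset_h") %||% 0
  local <- rtrack$timestamp + off * 3600
  ym <- format(local, "%Y-%m")
  segs <- lapply(split(seq_len(nrow(rtrack)), ym), function(i) {
    s <- rtrack[i, , drop = FALSE]
    if (!any(s$observed)) return(NULL)
    yr <- as.integer(substr(format(local[i[1]], "%Y-%m"), 1, 4))
    mo <- as.integer(substr(format(local[i[1]], "%Y-%m"), 6, 7))
    mfirst <- as.Date(sprintf("%d-%02d-01", yr, mo))
    ndays <- as.integer(format(seq(mfirst, by = "month", length.out = 2)[2] - 1, "%d"))
    attr(s, "grid_interval_h") <- attr(rtrack, "grid_interval_h")
    attr(s, "utc_offset_h") <- off
    attr(s, "year") <- yr
    attr(s, "month") <- mo
    attr(s, "n_fixes") <- sum(s$observed)
    attr(s, "window_h") <- ndays * 24
    class(s) <- c("month_segment", "regular_track", "data.frame")
    s
  })
  segs <- segs[!vapply(segs, is.null, TRUE)]
  segs[order(vapply(segs, function(s) attr(s, "year") * 100 + attr(s, "month"), 0))]
}

#' Write a track as a GeoJSON LineString for inspection
#'
#' @param track A track data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track_geojson <- function(track, path) {
  .validate_track(track)
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(bird_id = track$bird_id[1],
                      n_fixes = nrow(track),
                      start = format(min(track$timestamp), "%Y-%m-%dT%H:%M:%SZ"),
                      end = format(max(track$timestamp), "%Y-%m-%dT%H:%M:%SZ")),
    geometry = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(track)),
                                         function(i) c(track$lon[i], track$lat[i]))))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Round-trip a regular track through CSV
#'
#' @param rtrack A [regularize()]d track.
#' @param path CSV path.
#' @return `path` invisibly (for write); a `regular_track` (for read).
#' @export
write_regular_csv <- function(rtrack, path) {
  stopifnot(inherits(rtrack, "regular_track"))
  df <- as.data.frame(rtrack)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  df$grid_interval_h <- attr(rtrack, "grid_interval_h")
  df$utc_offset_h <- attr(rtrack, "utc_offset_h")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regular_csv
#' @export
read_regular_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(bird_id = df$bird_id, species = df$species,
                    age_class = df$age_class,
                    timestamp = as.POSIXct(df$timestamp, tz = "UTC",
                                           format = "%Y-%m-%dT%H:%M:%SZ"),
                    lon = df$lon, lat = df$lat, observed = df$observed,
                    stringsAsFactors = FALSE)
  attr(out, "grid_interval_h") <- df$grid_interval_h[1]
  attr(out, "utc_offset_h") <- df$utc_offset_h[1]
  class(out) <- c("regular_track", "data.frame")
  out
}
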
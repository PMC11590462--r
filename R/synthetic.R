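# Synthetic telemetry tracks with known movement parameters and known
# per-month residency labels. The OUF simulator is the generative counterpart
# of the variogram model fitted by fit_ouf(); nomadic and diel tracks provide
# negative controls and constructed daily-metric truths.

#' Simulation configuration for a resident (OUF) track
#'
#' @param sigma2 Per-axis stationary positional variance (km^2).
#' @param tau_p Positional decorrelation timescale (hours). Must exceed `tau_v`.
#' @param tau_v Velocity decorrelation timescale (hours).
#' @param fix_interval_h Sampling step (hours).
#' @param duration_days Total track span (days); must be at least
#'   `2 * fix_interval_h` worth of time.
#' @param centre Home-range centre, `c(lon, lat)` in decimal degrees.
#' @param start POSIXct (UTC) time of the first fix.
#' @param bird_id,species,age_class,utc_offset_h Track metadata.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(sigma2, tau_p, tau_v, fix_interval_h = 6,
                       duration_days = 30, centre = c(145, -35),
                       start = as.POSIXct("2021-01-01 00:00:00", tz = "UTC"),
                       bird_id = "sim1", species = "SNI", age_class = "adult",
                       utc_offset_h = 10, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (!(tau_p > tau_v) || !(tau_v > 0)) stop("require tau_p > tau_v > 0")
  if (fix_interval_h <= 0) stop("fix_interval_h must be > 0")
  if (duration_days <= 0) stop("duration_days must be > 0")
  if (duration_days * 24 < 2 * fix_interval_h)
    stop("duration shorter than two fix intervals")
  structure(list(sigma2 = sigma2, tau_p = tau_p, tau_v = tau_v,
                 fix_interval_h = fix_interval_h, duration_days = duration_days,
                 centre = centre, start = start, bird_id = bird_id,
                 species = species, age_class = age_class,
                 utc_offset_h = utc_offset_h, seed = seed),
            class = "sim_config")
}

# Exact discrete-time transition of the per-axis (position, velocity) system.
# The OUF position process has autocovariance
#   C(tau) = sigma2 * (tau_p e^{-tau/tau_p} - tau_v e^{-tau/tau_v}) / (tau_p - tau_v),
# i.e. the stationary solution of the linear SDE
#   (d/dt + 1/tau_p)(d/dt + 1/tau_v) x = w(t).
# State z = (x, v): stationary covariance Pi = diag(sigma2, sigma2/(tau_p*tau_v)),
# transition Phi = expm(A dt) in closed form (distinct eigenvalues -1/tau_p,
# -1/tau_v), and exact innovation covariance Q = Pi - Phi Pi Phi'.
.ouf_discrete_system <- function(sigma2, tau_p, tau_v, dt) {
  r1 <- -1 / tau_p; r2 <- -1 / tau_v
  A <- matrix(c(0, -1 / (tau_p * tau_v), 1, -(1 / tau_p + 1 / tau_v)), 2, 2)
  I2 <- diag(2)
  Phi <- (exp(r1 * dt) * (A - r2 * I2) - exp(r2 * dt) * (A - r1 * I2)) / (r1 - r2)
  Pi <- diag(c(sigma2, sigma2 / (tau_p * tau_v)))
  Q <- Pi - Phi %*% Pi %*% t(Phi)
  Q <- (Q + t(Q)) / 2
  list(Phi = Phi, Pi = Pi, Q = Q)
}

# lower-triangular square root of a 2x2 PSD matrix (tolerant Cholesky)
.chol2 <- function(S) {
  a <- max(S[1, 1], 0)
  l11 <- sqrt(a)
  l21 <- if (l11 > 0) S[2, 1] / l11 else 0
  l22 <- sqrt(max(S[2, 2] - l21^2, 0))
  matrix(c(l11, l21, 0, l22), 2, 2)
}

# Core per-axis OUF sampler: returns n positions (km). init = NULL draws the
# stationary state; otherwise init = c(x0, v0) conditions the start.
.sim_ouf_axis <- function(n, sigma2, tau_p, tau_v, dt, init = NULL) {
  sys <- .ouf_discrete_system(sigma2, tau_p, tau_v, dt)
  Lq <- .chol2(sys$Q)
  z <- matrix(0, 2, n)
  z[, 1] <- if (is.null(init)) .chol2(sys$Pi) %*% rnorm(2) else init
  if (n > 1) {
    eps <- matrix(rnorm(2 * (n - 1)), 2)
    for (k in 2:n) z[, k] <- sys$Phi %*% z[, k - 1] + Lq %*% eps[, k - 1]
  }
  z
}

.track_df <- function(times, lonlat, config) {
  data.frame(bird_id = config$bird_id, species = config$species,
             age_class = config$age_class, timestamp = times,
             lon = lonlat[, 1], lat = lonlat[, 2],
             utc_offset_h = config$utc_offset_h,
             stringsAsFactors = FALSE)
}

# shared internal used by both simulate_ouf_track and simulate_mixed_track so
# that a single all-resident schedule reproduces simulate_ouf_track exactly
.simulate_ouf_core <- function(config, times, init_xy = NULL) {
  n <- length(times)
  if (config$sigma2 == 0) {
    xy <- matrix(0, n, 2)
  } else {
    init_x <- init_y <- NULL
    if (!is.null(init_xy)) {
      v_sd <- sqrt(config$sigma2 / (config$tau_p * config$tau_v))
      init_x <- c(init_xy[1], rnorm(1, 0, v_sd))
      init_y <- c(init_xy[2], rnorm(1, 0, v_sd))
    }
    zx <- .sim_ouf_axis(n, config$sigma2, config$tau_p, config$tau_v,
                        config$fix_interval_h, init_x)
    zy <- .sim_ouf_axis(n, config$sigma2, config$tau_p, config$tau_v,
                        config$fix_interval_h, init_y)
    xy <- cbind(zx[1, ], zy[1, ])
  }
  xy
}

#' Simulate a resident track from the OUF movement model
#'
#' Exact simulation of the isotropic Ornstein-Uhlenbeck-Foraging process:
#' each axis is a stationary (position, velocity) linear Gaussian system
#' sampled through its exact discrete-time transition, so there is no Euler
#' discretisation error at any fix interval. Planar km displacements are
#' inverse-projected (azimuthal equidistant) about `centre`.
#'
#' @param config A [sim_config()].
#' @return A track `data.frame` with columns `bird_id`, `species`,
#'   `age_class`, `timestamp` (POSIXct UTC), `lon`, `lat`, `utc_offset_h`.
#' @examples
#' trk <- simulate_ouf_track(sim_config(sigma2 = 100, tau_p = 24, tau_v = 1,
#'                                      duration_days = 10, seed = 1))
#' @export
simulate_ouf_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  times <- config$start +
    seq(0, config$duration_days * 86400, by = config$fix_interval_h * 3600)
  xy <- .simulate_ouf_core(config, times)
  .track_df(times, unproject_aeqd(xy, config$centre), config)
}

#' Simulate a nomadic (ballistic) track
#'
#' Correlated-heading random walk: headings evolve as a wrapped Gaussian walk
#' whose concentration is set so that `E[cos(turning angle)] =
#' heading_persistence`; step length is `speed_kmh * fix_interval_h`. Net
#' displacement grows without bound, so the semivariance function has no
#' asymptote within a month -- the negative control for residency.
#'
#' @param speed_kmh Travel speed (km/h), > 0 (0 allowed: stationary track).
#' @param heading_persistence In `[0, 1)`; 0 gives independent headings.
#' @param duration_days,fix_interval_h,centre,start Track layout, as in
#'   [sim_config()].
#' @param seed Integer RNG seed or `NULL`.
#' @param bird_id,species,age_class,utc_offset_h Track metadata.
#' @return A track `data.frame` (same schema as [simulate_ouf_track()]).
#' @export
simulate_nomadic_track <- function(speed_kmh, heading_persistence = 0.9,
                                   duration_days = 30, fix_interval_h = 6,
                                   centre = c(145, -35),
                                   start = as.POSIXct("2021-01-01 00:00:00", tz = "UTC"),
                                   seed = NULL, bird_id = "nomad1",
                                   species = "SNI", age_class = "adult",
                                   utc_offset_h = 10) {
  if (speed_kmh < 0) stop("speed_kmh must be >= 0")
  if (heading_persistence < 0 || heading_persistence >= 1)
    stop("heading_persistence must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  times <- start + seq(0, duration_days * 86400, by = fix_interval_h * 3600)
  n <- length(times)
  if (heading_persistence == 0) {
    theta <- runif(n - 1, 0, 2 * pi)
  } else {
    # wrapped-normal turning angles: E[cos] = exp(-s^2/2) = persistence
    s <- sqrt(-2 * log(heading_persistence))
    theta <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 2, 0, s)))
  }
  step <- speed_kmh * fix_interval_h
  xy <- cbind(c(0, cumsum(step * cos(theta))), c(0, cumsum(step * sin(theta))))
  cfg <- list(bird_id = bird_id, species = species, age_class = age_class,
              utc_offset_h = utc_offset_h)
  .track_df(times, unproject_aeqd(xy, centre), cfg)
}

#' Build a movement-mode schedule
#'
#' @param segments A list of lists with fields `start`, `end` (Dates or
#'   anything coercible), `mode` (`"resident"` or `"nomadic"`), and `params`
#'   (a list passed to the segment simulator).
#' @return Validated list of class `"mode_schedule"`.
#' @export
mode_schedule <- function(segments) {
  starts <- as.Date(vapply(segments, function(s) as.character(as.Date(s$start)), ""))
  ends <- as.Date(vapply(segments, function(s) as.character(as.Date(s$end)), ""))
  modes <- vapply(segments, function(s) s$mode, "")
  if (!all(modes %in% c("resident", "nomadic"))) stop("unknown mode")
  if (any(ends <= starts)) stop("segment end must follow start")
  if (length(segments) > 1) {
    if (is.unsorted(as.numeric(starts), strictly = TRUE))
      stop("segments must be chronologically ordered")
    if (any(starts[-1] != ends[-length(ends)]))
      stop("gap or overlap in schedule: segments must tile the span")
  }
  structure(segments, class = "mode_schedule")
}

#' Simulate a mixed-strategy track with known monthly labels
#'
#' Concatenates resident (OUF) and nomadic segments with positional continuity
#' at the boundaries: each segment starts where the previous one ended
#' (resident segments re-centre their home range there). The truth label of a
#' calendar month is the mode occupying the majority of its days.
#'
#' @param schedule A [mode_schedule()]. Resident segments take params
#'   `sigma2`, `tau_p`, `tau_v`; nomadic segments `speed_kmh`,
#'   `heading_persistence`.
#' @param seed Integer RNG seed.
#' @param fix_interval_h Sampling step (hours).
#' @param centre Starting `c(lon, lat)`.
#' @param bird_id,species,age_class,utc_offset_h Track metadata.
#' @return A list with `track` (fix data.frame) and `labels`
#'   (`data.frame(bird_id, year, month, mode)`).
#' @export
simulate_mixed_track <- function(schedule, seed = NULL, fix_interval_h = 6,
                                 centre = c(145, -35), bird_id = "mix1",
                                 species = "SNI", age_class = "adult",
                                 utc_offset_h = 10) {
  stopifnot(inherits(schedule, "mode_schedule"))
  if (!is.null(seed)) set.seed(seed)
  t0 <- as.POSIXct(paste(as.Date(schedule[[1]]$start), "00:00:00"), tz = "UTC")
  t_end <- as.POSIXct(paste(as.Date(schedule[[length(schedule)]]$end), "00:00:00"),
                      tz = "UTC")
  times <- seq(t0, t_end, by = fix_interval_h * 3600)
  pos <- matrix(NA_real_, length(times), 2)   # km plane about `centre`
  cur <- c(0, 0)
  meta <- list(bird_id = bird_id, species = species, age_class = age_class,
               utc_offset_h = utc_offset_h)
  for (si in seq_along(schedule)) {
    seg <- schedule[[si]]
    s_start <- as.POSIXct(paste(as.Date(seg$start), "00:00:00"), tz = "UTC")
    s_end <- as.POSIXct(paste(as.Date(seg$end), "00:00:00"), tz = "UTC")
    idx <- which(times >= s_start & (times < s_end | (si == length(schedule) & times <= s_end)))
    n <- length(idx)
    if (n == 0) next
    if (seg$mode == "resident") {
      p <- seg$params
      cfg <- list(sigma2 = p$sigma2, tau_p = p$tau_p, tau_v = p$tau_v,
                  fix_interval_h = fix_interval_h)
      if (si == 1) {
        xy <- .simulate_ouf_core(cfg, times[idx])           # stationary start
        off <- cur
      } else {
        xy <- .simulate_ouf_core(cfg, times[idx], init_xy = c(0, 0))
        off <- cur                                          # home = entry point
      }
      seg_xy <- sweep(xy, 2, off, "+")
    } else {
      p <- seg$params
      rho <- if (is.null(p$heading_persistence)) 0.9 else p$heading_persistence
      if (rho == 0) theta <- runif(n - 1, 0, 2 * pi)
      else {
        s <- sqrt(-2 * log(rho))
        theta <- cumsum(c(runif(1, 0, 2 * pi), rnorm(max(n - 2, 0), 0, s)))
      }
      step <- p$speed_kmh * fix_interval_h
      seg_xy <- cbind(c(0, cumsum(step * cos(theta)))[seq_len(n)],
                      c(0, cumsum(step * sin(theta)))[seq_len(n)])
      seg_xy <- sweep(seg_xy, 2, cur, "+")
    }
    pos[idx, ] <- seg_xy
    cur <- seg_xy[n, ]
  }
  track <- .track_df(times, unproject_aeqd(pos, centre), meta)

  # majority-of-month truth labels over the schedule span
  days <- seq(as.Date(schedule[[1]]$start), as.Date(schedule[[length(schedule)]]$end) - 1,
              by = "day")
  day_mode <- character(length(days))
  for (seg in schedule) {
    inseg <- days >= as.Date(seg$start) & days < as.Date(seg$end)
    day_mode[inseg] <- seg$mode
  }
  ym <- format(days, "%Y-%m")
  lab <- vapply(split(day_mode, ym), function(m) names(which.max(table(m))), "")
  labels <- data.frame(bird_id = bird_id,
                       year = as.integer(substr(names(lab), 1, 4)),
                       month = as.integer(substr(names(lab), 6, 7)),
                       mode = unname(lab), stringsAsFactors = FALSE)
  list(track = track, labels = labels)
}

#' Simulate a diel roost-forage track with constructed daily truths
#'
#' The bird sits at its roost at every local midnight (and through the night),
#' and spends local daytime (06:00-18:00) at a foraging site drawn at exactly
#' `forage_distance_km` from the roost in a uniformly random direction each
#' day. Optionally the roost itself shifts by exactly `roost_shift_km` (random
#' direction) at each midnight.
#'
#' @param roost_lonlat `c(lon, lat)` of the initial roost.
#' @param forage_distance_km Distance to the daily foraging site (>= 0).
#' @param duration_days,fix_interval_h Track layout; the grid is anchored at
#'   local midnight so a midnight fix always exists when `fix_interval_h`
#'   divides 24.
#' @param seed Integer RNG seed.
#' @param roost_shift_km Roost displacement applied at each local midnight.
#' @param bird_id,species,age_class,utc_offset_h Track metadata.
#' @return A track `data.frame`; attribute `"truth"` holds
#'   `data.frame(date, max_from_roost_km, roost_shift_km)`.
#' @export
simulate_diel_track <- function(roost_lonlat, forage_distance_km,
                                duration_days = 30, fix_interval_h = 1,
                                seed = NULL, roost_shift_km = 0,
                                bird_id = "diel1", species = "AWI",
                                age_class = "adult", utc_offset_h = 10) {
  if (forage_distance_km < 0) stop("forage_distance_km must be >= 0")
  if (roost_shift_km < 0) stop("roost_shift_km must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  # start at a local midnight: UTC time = -offset
  t0 <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC") - utc_offset_h * 3600
  times <- t0 + seq(0, duration_days * 86400 - 1, by = fix_interval_h * 3600)
  local <- times + utc_offset_h * 3600
  lh <- as.numeric(format(local, "%H")) + as.numeric(format(local, "%M")) / 60
  lday <- as.Date(format(local, "%Y-%m-%d"))
  days <- sort(unique(lday))
  nd <- length(days)
  th_f <- runif(nd, 0, 2 * pi)
  th_r <- runif(nd, 0, 2 * pi)
  roost <- matrix(0, nd, 2)
  for (d in seq_len(nd)[-1])
    roost[d, ] <- roost[d - 1, ] + roost_shift_km * c(cos(th_r[d]), sin(th_r[d]))
  forage <- roost + forage_distance_km * cbind(cos(th_f), sin(th_f))
  di <- match(lday, days)
  daytime <- lh >= 6 & lh < 18
  xy <- ifelse(cbind(daytime, daytime), forage[di, , drop = FALSE],
               roost[di, , drop = FALSE])
  cfg <- list(bird_id = bird_id, species = species, age_class = age_class,
              utc_offset_h = utc_offset_h)
  out <- .track_df(times, unproject_aeqd(xy, roost_lonlat), cfg)
  attr(out, "truth") <- data.frame(
    date = days,
    max_from_roost_km = ifelse(vapply(seq_len(nd), function(d) any(daytime[di == d]), TRUE),
                               forage_distance_km, 0),
    roost_shift_km = c(NA, rep(roost_shift_km, nd - 1)))
  out
}

#' Closed-form autocovariance of the OUF position process
#'
#' `C(tau) = sigma2 * (tau_p exp(-tau/tau_p) - tau_v exp(-tau/tau_v)) /
#' (tau_p - tau_v)`; used by the simulator and as the oracle for the
#' semivariance function, `gamma(tau) = C(0) - C(tau)`.
#'
#' @param tau Lag(s), hours.
#' @param sigma2,tau_p,tau_v OUF parameters.
#' @return Autocovariance in km^2 per axis.
#' @export
ouf_acov <- function(tau, sigma2, tau_p, tau_v) {
  sigma2 * (tau_p * exp(-tau / tau_p) - tau_v * exp(-tau / tau_v)) / (tau_p - tau_v)
}
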
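# Autocorrelated kernel density estimation of residency areas, 95% contours,
# Bhattacharyya overlap with parametric-bootstrap CIs, and merging of
# overlapping resident months into blocks.

#' Autocorrelation-corrected effective sample size
#'
#' `N_eff = span / tau_p`, floored at 1 and capped at the number of fixes,
#' where `span = n_fixes * fix_interval`. This is the number of statistically
#' independent locations contributed by an autocorrelated track and drives
#' the AKDE bandwidth.
#'
#' @param n_fixes Number of fixes (> 0).
#' @param fix_interval_h Sampling interval (hours, > 0).
#' @param tau_p_h Positional decorrelation timescale (hours, > 0).
#' @return Effective sample size (numeric, in `[1, n_fixes]`).
#' @export
effective_n <- function(n_fixes, fix_interval_h, tau_p_h) {
  stopifnot(n_fixes > 0, fix_interval_h > 0, tau_p_h > 0)
  min(max(n_fixes * fix_interval_h / tau_p_h, 1), n_fixes)
}

#' Autocorrelated kernel density estimate of a utilisation distribution
#'
#' Gaussian-kernel density on the local plane with the bivariate-normal
#' reference bandwidth corrected for autocorrelation: per axis,
#' `h^2 = s^2 * N_eff^{-1/3}` with `s^2` the sample variance and `N_eff` from
#' [effective_n()] using the fitted `tau_p`. The grid is auto-sized to
#' `+/- 4 (s + h)` about the mean position.
#'
#' @param xy Two-column matrix of planar positions (km), e.g. from
#'   [project_aeqd()].
#' @param fit An [fit_ouf()] result supplying `tau_p_hat`.
#' @param fix_interval_h Sampling interval of `xy` (hours).
#' @param cell_km Grid cell size; default auto (extent/160, at most `h/2`).
#' @param centre Projection centre `c(lon, lat)` used for `xy` (kept so
#'   contours can be returned in geographic coordinates).
#' @param period Optional two-element vector (start, end) recorded on the UD.
#' @param bird_id Recorded on the UD.
#' @return A `ud` object: list with `x`, `y` (cell-centre coordinates, km),
#'   `p` (cell mass matrix, sums to 1), `cell_km`, `mu`, `Sigma` (Gaussian
#'   summary), `h2` (squared bandwidths), `n_eff`, `centre`, `point_mass`
#'   flag, `bird_id`, `period`.
#' @export
akde_ud <- function(xy, fit, fix_interval_h = 6, cell_km = NULL,
                    centre = c(0, 0), period = NULL, bird_id = NA_character_) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  n <- nrow(xy)
  mu <- colMeans(xy)
  if (n < 2 || all(abs(sweep(xy, 2, mu)) < 1e-9)) {
    return(structure(list(x = mu[1], y = mu[2], p = matrix(1, 1, 1),
                          cell_km = cell_km %||% 0.1, mu = mu,
                          Sigma = diag(1e-12, 2), h2 = c(0, 0), n_eff = 1,
                          centre = centre, point_mass = TRUE,
                          bird_id = bird_id, period = period), class = "ud"))
  }
  S <- stats::cov(xy)
  tau_p <- if (!is.null(fit$tau_p_hat) && is.finite(fit$tau_p_hat))
    fit$tau_p_hat else fix_interval_h
  n_eff <- effective_n(n, fix_interval_h, tau_p)
  # mean-estimation debias: under autocorrelation the sample covariance loses
  # ~ var(sample mean) = (2/N_eff)(1 - 1/N_eff) sigma^2 per axis; the debiased
  # covariance is the area target, while bandwidth and the smoothed density
  # reflect the raw scatter actually on the grid
  S_deb <- if (n_eff > 4) S / (1 - (2 / n_eff) * (1 - 1 / n_eff)) else S
  h2 <- diag(S) * n_eff^(-1 / 3)
  s <- sqrt(diag(S)); h <- sqrt(h2)
  half <- 4 * (s + h)
  if (is.null(cell_km)) cell_km <- max(min(2 * half) / 160, min(h) / 2 / 4)
  gx <- seq(mu[1] - half[1], mu[1] + half[1], by = cell_km)
  gy <- seq(mu[2] - half[2], mu[2] + half[2], by = cell_km)
  # separable Gaussian kernels: density = Ex' Ey with Ex[i, ] the x-kernel of
  # fix i evaluated on gx (one BLAS crossprod instead of n outer products)
  Ex <- vapply(gx, function(g) stats::dnorm(g, xy[, 1], h[1]), numeric(n))
  Ey <- vapply(gy, function(g) stats::dnorm(g, xy[, 2], h[2]), numeric(n))
  dens <- crossprod(Ex, Ey) / n
  p <- dens * cell_km^2
  p <- p / sum(p)
  structure(list(x = gx, y = gy, p = p, cell_km = cell_km, mu = mu,
                 Sigma = S + diag(h2), h2 = h2, n_eff = n_eff, centre = centre,
                 point_mass = FALSE, bird_id = bird_id, period = period,
                 Sigma_sample = S_deb),
            class = "ud")
}

#' Build a UD object from an exact bivariate Gaussian (oracle helper)
#'
#' @param mu Mean `c(x, y)` (km).
#' @param Sigma 2x2 covariance (km^2).
#' @param cell_km Cell size.
#' @param extent_sd Half-width of the grid in standard deviations (default 5).
#' @param centre Projection centre lon/lat.
#' @param n_eff Recorded effective sample size.
#' @return A `ud` object whose Gaussian summary is exactly (`mu`, `Sigma`).
#' @export
ud_from_gaussian <- function(mu, Sigma, cell_km = NULL, extent_sd = 5,
                             centre = c(0, 0), n_eff = Inf) {
  s <- sqrt(diag(Sigma))
  if (is.null(cell_km)) cell_km <- min(s) / 15
  gx <- seq(mu[1] - extent_sd * s[1], mu[1] + extent_sd * s[1], by = cell_km)
  gy <- seq(mu[2] - extent_sd * s[2], mu[2] + extent_sd * s[2], by = cell_km)
  Si <- solve(Sigma)
  dx <- outer(gx - mu[1], rep(1, length(gy)))
  dy <- outer(rep(1, length(gx)), gy - mu[2])
  q <- Si[1, 1] * dx^2 + 2 * Si[1, 2] * dx * dy + Si[2, 2] * dy^2
  p <- exp(-q / 2)
  p <- p / sum(p)
  structure(list(x = gx, y = gy, p = p, cell_km = cell_km, mu = mu,
                 Sigma = Sigma, h2 = c(0, 0), n_eff = n_eff, centre = centre,
                 point_mass = FALSE, bird_id = NA_character_, period = NULL,
                 Sigma_sample = Sigma),
            class = "ud")
}

#' Highest-density-region contour area of a UD
#'
#' The level-`level` region is the smallest set of cells whose total mass
#' reaches `level`; its raw area is cell count x cell area. Because the
#' reference-rule bandwidth smears the UD by `h^2` per axis, the raw area
#' overestimates the underlying range area (Gaussian HDR areas scale with
#' `sqrt(det Sigma)`); with `debias = TRUE` (default) the reported area is
#' multiplied by `sqrt(det(S_sample) / det(S_smoothed))`, restoring the
#' unsmoothed scale.
#'
#' @param ud A `ud` object.
#' @param level Coverage level in (0, 1), default 0.95.
#' @param debias Apply the bandwidth-area correction (default `TRUE`).
#' @return A list with `area_km2` (debiased if requested), `area_raw_km2`,
#'   `polygon` (list of rings, two-column lon/lat matrices), `threshold`
#'   (density at the contour), `level`.
#' @export
contour_area <- function(ud, level = 0.95, debias = TRUE) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  stopifnot(inherits(ud, "ud"))
  if (isTRUE(ud$point_mass)) {
    return(list(area_km2 = 0, area_raw_km2 = 0, polygon = list(),
                threshold = Inf, level = level, point_mass = TRUE))
  }
  ord <- order(ud$p, decreasing = TRUE)
  cum <- cumsum(ud$p[ord])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(ord)
  area_raw <- k * ud$cell_km^2
  thr_mass <- ud$p[ord[k]]
  corr <- 1
  if (debias && !is.null(ud$Sigma_sample)) {
    d_sm <- det(ud$Sigma); d_sa <- det(ud$Sigma_sample)
    if (is.finite(d_sm) && d_sm > 0 && is.finite(d_sa) && d_sa > 0)
      corr <- sqrt(d_sa / d_sm)
  }
  dens <- ud$p / ud$cell_km^2
  rings <- tryCatch(
    suppressWarnings(grDevices::contourLines(ud$x, ud$y, dens,
                                             levels = thr_mass / ud$cell_km^2)),
    error = function(e) list())   # flat densities have no iso-contour
  polygon <- lapply(rings, function(r)
    unproject_aeqd(cbind(r$x, r$y), ud$centre))
  list(area_km2 = area_raw * corr, area_raw_km2 = area_raw, polygon = polygon,
       threshold = thr_mass / ud$cell_km^2, level = level, point_mass = FALSE)
}

# resample a UD's density onto given cell-centre vectors (nearest cell,
# zero outside its grid), returning a mass matrix
.resample_ud <- function(ud, gx, gy) {
  ix <- round((gx - ud$x[1]) / ud$cell_km) + 1
  iy <- round((gy - ud$y[1]) / ud$cell_km) + 1
  okx <- ix >= 1 & ix <= length(ud$x)
  oky <- iy >= 1 & iy <= length(ud$y)
  m <- matrix(0, length(gx), length(gy))
  if (any(okx) && any(oky)) {
    dens <- ud$p / ud$cell_km^2
    m[okx, oky] <- dens[ix[okx], iy[oky]]
  }
  m
}

#' Bhattacharyya coefficient between two UDs (grid sum)
#'
#' `BC = sum_cells sqrt(p_i q_i)` after resampling both UDs onto a common
#' grid covering the union of their supports. Returns 0 (with a warning) for
#' disjoint grids.
#'
#' @param ud1,ud2 `ud` objects built about the same projection centre.
#' @return The Bhattacharyya coefficient in `[0, 1]`.
#' @seealso [bhattacharyya_gaussian()] for the closed form used by the
#'   bootstrap CI path.
#' @export
bhattacharyya <- function(ud1, ud2) {
  stopifnot(inherits(ud1, "ud"), inherits(ud2, "ud"))
  cell <- min(ud1$cell_km, ud2$cell_km)
  x0 <- min(ud1$x[1], ud2$x[1]); x1 <- max(max(ud1$x), max(ud2$x))
  y0 <- min(ud1$y[1], ud2$y[1]); y1 <- max(max(ud1$y), max(ud2$y))
  if (x1 <= x0 || y1 <= y0 ||
      (min(ud1$x) > max(ud2$x) + cell) || (min(ud2$x) > max(ud1$x) + cell) ||
      (min(ud1$y) > max(ud2$y) + cell) || (min(ud2$y) > max(ud1$y) + cell)) {
    warning("UD grids are disjoint; BC = 0")
    return(0)
  }
  gx <- seq(x0, x1, by = cell)
  gy <- seq(y0, y1, by = cell)
  p <- .resample_ud(ud1, gx, gy); p <- p / sum(p)
  q <- .resample_ud(ud2, gx, gy); q <- q / sum(q)
  sum(sqrt(p * q))
}

#' Closed-form Bhattacharyya coefficient of two Gaussians
#'
#' `BC = exp(-D_B)` with
#' `D_B = (1/8) dmu' Sbar^{-1} dmu + (1/2) log(det Sbar / sqrt(det S1 det S2))`,
#' `Sbar = (S1 + S2)/2`.
#'
#' @param mu1,mu2 Mean vectors.
#' @param S1,S2 2x2 covariance matrices.
#' @return BC in `[0, 1]`.
#' @export
bhattacharyya_gaussian <- function(mu1, S1, mu2, S2) {
  Sb <- (S1 + S2) / 2
  dm <- mu1 - mu2
  db <- sum(dm * solve(Sb, dm)) / 8 +
    0.5 * log(det(Sb) / sqrt(det(S1) * det(S2)))
  exp(-db)
}

#' Bootstrap confidence interval for the Bhattacharyya coefficient
#'
#' Parametric bootstrap on the Gaussian approximations of the two UDs:
#' each replicate draws a mean from its sampling distribution
#' (`N(mu, Sigma / N_eff)`) and a covariance from the Wishart sampling
#' distribution (`W(N_eff - 1, Sigma / (N_eff - 1))`), then recomputes the
#' closed-form BC. CI bounds are the 2.5% / 97.5% bootstrap percentiles
#' (clamped so `ci_low <= bc <= ci_high`). With `N_eff < 2` in either UD the
#' CI is undefined and the overlap test fails closed (`ok = FALSE`).
#'
#' @param ud1,ud2 `ud` objects (same projection centre).
#' @param n_boot Bootstrap replicates, default 200.
#' @param seed Integer RNG seed or `NULL`.
#' @return A list with `bc`, `ci_low`, `ci_high`, `ok`, `n_boot`.
#' @export
bc_confidence <- function(ud1, ud2, n_boot = 200, seed = NULL) {
  stopifnot(inherits(ud1, "ud"), inherits(ud2, "ud"))
  bc <- bhattacharyya_gaussian(ud1$mu, ud1$Sigma, ud2$mu, ud2$Sigma)
  if (isTRUE(ud1$point_mass) || isTRUE(ud2$point_mass) ||
      min(ud1$n_eff, ud2$n_eff) < 2) {
    return(list(bc = bc, ci_low = NA_real_, ci_high = NA_real_, ok = FALSE,
                n_boot = 0L))
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(ud) {
    ne <- min(ud$n_eff, 1e6)
    L <- .chol2(ud$Sigma / ne)
    mu <- ud$mu + as.numeric(L %*% rnorm(2))
    df <- max(ne - 1, 2.01)
    S <- stats::rWishart(1, df, ud$Sigma / df)[, , 1]
    list(mu = mu, S = S)
  }
  reps <- vapply(seq_len(n_boot), function(i) {
    a <- draw(ud1); b <- draw(ud2)
    bhattacharyya_gaussian(a$mu, a$S, b$mu, b$S)
  }, 0)
  qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  list(bc = bc, ci_low = min(qs[1], bc), ci_high = max(qs[2], bc), ok = TRUE,
       n_boot = n_boot)
}

#' Merge consecutive overlapping resident months into residency blocks
#'
#' For one bird: consecutive resident calendar months whose monthly UDs
#' overlap (BC lower confidence bound > `ci_threshold`) are chained into a
#' block; for each closed block the OUF model is refitted and the AKDE rerun
#' on the pooled fixes, giving the block's joint 95% residency area. With
#' `chain = FALSE`, only pairwise merges are made (a block never grows past
#' two months).
#'
#' @param track A single bird's track data.frame.
#' @param calls Optional precomputed residency calls for this bird (from
#'   [classify_all_months()]); computed if `NULL`.
#' @param grid_interval_h,tolerance_min,min_fixes Preprocessing parameters.
#' @param ci_threshold Overlap rule: merge when `ci_low > ci_threshold`
#'   (default 0.01).
#' @param n_boot,seed Passed to [bc_confidence()].
#' @param cell_km Optional AKDE cell size.
#' @param chain Transitive chaining of consecutive overlaps (default `TRUE`).
#' @return A `data.frame` with one row per block: `bird_id`, `block_id`,
#'   `start_month`, `end_month`, `n_months`, `n_fixes`, `area95_km2`;
#'   attributes `polygons` (per-block contour rings) and `uds`.
#' @export
merge_blocks <- function(track, calls = NULL, grid_interval_h = 6,
                         tolerance_min = 90, min_fixes = 20,
                         ci_threshold = 0.01, n_boot = 200, seed = NULL,
                         cell_km = NULL, chain = TRUE) {
  .validate_track(track)
  if (is.null(calls)) calls <- classify_all_months(track, grid_interval_h,
                                                   tolerance_min, min_fixes)
  calls <- calls[calls$bird_id == track$bird_id[1], , drop = FALSE]
  rt <- regularize(track, grid_interval_h, tolerance_min)
  segs <- split_months(rt)
  seg_key <- vapply(segs, function(s) attr(s, "year") * 100 + attr(s, "month"), 0)
  res <- calls[!is.na(calls$resident) & calls$resident, , drop = FALSE]
  if (nrow(res) == 0) return(.empty_blocks())
  res <- res[order(res$year, res$month), , drop = FALSE]
  centre <- c(mean(track$lon), mean(track$lat))   # one plane per bird
  month_ud <- function(row) {
    seg <- segs[[match(row$year * 100 + row$month, seg_key)]]
    obs <- seg[seg$observed, , drop = FALSE]
    xy <- project_aeqd(obs$lon, obs$lat, centre)
    fit <- list(tau_p_hat = row$tau_p_hat)
    akde_ud(xy, fit, grid_interval_h, cell_km, centre,
            bird_id = row$bird_id)
  }
  uds <- lapply(seq_len(nrow(res)), function(i) month_ud(res[i, ]))
  # consecutive-in-calendar pairs of resident months
  ymnum <- res$year * 12 + res$month
  merge_next <- rep(FALSE, nrow(res))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(nrow(res) - 1)) {
    if (ymnum[i + 1] - ymnum[i] != 1) next      # gap month: never merged
    bcci <- bc_confidence(uds[[i]], uds[[i + 1]], n_boot = n_boot, seed = NULL)
    merge_next[i] <- isTRUE(bcci$ok) && bcci$ci_low > ci_threshold
  }
  if (!chain && any(merge_next)) {              # pairwise-only merging
    i <- 1
    while (i < length(merge_next)) {
      if (merge_next[i]) merge_next[i + 1] <- FALSE
      i <- i + 1
    }
  }
  block_id <- cumsum(c(TRUE, !merge_next[-length(merge_next)]))
  rows <- list(); polys <- list(); block_uds <- list()
  for (b in unique(block_id)) {
    members <- which(block_id == b)
    pooled <- do.call(rbind, lapply(members, function(i) {
      seg <- segs[[match(res$year[i] * 100 + res$month[i], seg_key)]]
      seg[seg$observed, c("timestamp", "lon", "lat")]
    }))
    pooled <- pooled[order(pooled$timestamp), , drop = FALSE]
    xy <- project_aeqd(pooled$lon, pooled$lat, centre)
    svf <- tryCatch(empirical_svf(data.frame(timestamp = pooled$timestamp,
                                             lon = pooled$lon, lat = pooled$lat)),
                    error = function(e) NULL)
    fit <- if (!is.null(svf)) fit_ouf(svf) else list(tau_p_hat = NA_real_)
    ud <- akde_ud(xy, fit, grid_interval_h, cell_km, centre,
                  bird_id = track$bird_id[1],
                  period = range(pooled$timestamp))
    ca <- contour_area(ud, 0.95)
    rows[[length(rows) + 1]] <- data.frame(
      bird_id = track$bird_id[1], block_id = b,
      start_month = sprintf("%d-%02d", res$year[members[1]], res$month[members[1]]),
      end_month = sprintf("%d-%02d", res$year[members[length(members)]],
                          res$month[members[length(members)]]),
      n_months = length(members), n_fixes = nrow(pooled),
      area95_km2 = ca$area_km2, stringsAsFactors = FALSE)
    polys[[length(polys) + 1]] <- ca$polygon
    block_uds[[length(block_uds) + 1]] <- ud
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "polygons") <- polys
  attr(out, "uds") <- block_uds
  out
}

.empty_blocks <- function() {
  out <- data.frame(bird_id = character(), block_id = integer(),
                    start_month = character(), end_month = character(),
                    n_months = integer(), n_fixes = integer(),
                    area95_km2 = numeric(), stringsAsFactors = FALSE)
  attr(out, "polygons") <- list()
  attr(out, "uds") <- list()
  out
}

#' Summaries of residency-block areas by group, with permutation tests
#'
#' @param blocks A blocks `data.frame` (rows from [merge_blocks()], possibly
#'   several birds' results combined with `rbind`).
#' @param group Grouping vector aligned with the rows (e.g. species x age).
#' @param statistic,n_perm,seed Passed to the pairwise permutation tests.
#' @return A list with `summary` (`data.frame(group, n, median_km2, mean_km2)`)
#'   and `tests` (Holm-adjusted p-value matrix, `NULL` with < 2 groups).
#' @export
block_summaries <- function(blocks, group = NULL, statistic = "median",
                            n_perm = 1000, seed = NULL) {
  if (is.null(group)) group <- rep("all", nrow(blocks))
  sp <- split(blocks$area95_km2, group)
  summary <- do.call(rbind, lapply(names(sp), function(g)
    data.frame(group = g, n = length(sp[[g]]),
               median_km2 = stats::median(sp[[g]]),
               mean_km2 = mean(sp[[g]]), stringsAsFactors = FALSE)))
  tests <- if (length(sp) >= 2)
    pairwise_percentile_tests(sp, statistic, n_perm, seed) else NULL
  list(summary = summary, tests = tests)
}
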
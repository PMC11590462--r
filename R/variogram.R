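# Empirical semivariance, OUF variogram fitting, and derivative-based
# monthly residency classification.
#
# Per-axis SVF convention: gamma(tau) = E[ |r(t+tau) - r(t)|^2 ] / (2 * d)
# with d = 2 dimensions, so that gamma(Inf) equals the per-axis stationary
# variance sigma^2 of a range-resident process.

#' Theoretical OUF semivariance function
#'
#' `gamma(tau) = sigma2 * [1 - (tau_p e^{-tau/tau_p} - tau_v e^{-tau/tau_v}) /
#' (tau_p - tau_v)]`, the semivariogram of the Ornstein-Uhlenbeck-Foraging
#' process. The continuous limit `sigma2 * [1 - e^{-tau/tau_p}(1 + tau/tau_p)]`
#' is used when the timescales coincide numerically. As `tau_v -> 0` the OU
#' form `sigma2 * (1 - e^{-tau/tau_p})` is recovered.
#'
#' @param tau Lag(s) in hours, >= 0.
#' @param sigma2 Asymptotic per-axis variance (km^2).
#' @param tau_p,tau_v Positional and velocity timescales (hours),
#'   `tau_p > tau_v > 0`.
#' @return Semivariance in km^2 (per axis).
#' @export
ouf_svf <- function(tau, sigma2, tau_p, tau_v) {
  if (any(tau < 0)) stop("tau must be >= 0")
  if (!(tau_p > 0) || !(tau_v > 0) || tau_p < tau_v)
    stop("require tau_p >= tau_v > 0")
  if ((tau_p - tau_v) < 1e-8 * tau_p) {
    return(sigma2 * (1 - exp(-tau / tau_p) * (1 + tau / tau_p)))
  }
  sigma2 * (1 - (tau_p * exp(-tau / tau_p) - tau_v * exp(-tau / tau_v)) /
              (tau_p - tau_v))
}

#' First and second derivatives of the OUF semivariance
#'
#' `gamma'(tau) = sigma2 (e^{-tau/tau_p} - e^{-tau/tau_v}) / (tau_p - tau_v)`;
#' `gamma''(tau) = sigma2 (e^{-tau/tau_v}/tau_v - e^{-tau/tau_p}/tau_p) /
#' (tau_p - tau_v)`.
#'
#' @inheritParams ouf_svf
#' @return Derivative value(s), km^2/h (first) or km^2/h^2 (second).
#' @export
ouf_svf_d1 <- function(tau, sigma2, tau_p, tau_v) {
  sigma2 * (exp(-tau / tau_p) - exp(-tau / tau_v)) / (tau_p - tau_v)
}

#' @rdname ouf_svf_d1
#' @export
ouf_svf_d2 <- function(tau, sigma2, tau_p, tau_v) {
  sigma2 * (exp(-tau / tau_v) / tau_v - exp(-tau / tau_p) / tau_p) / (tau_p - tau_v)
}

#' Empirical semivariance function of a month segment
#'
#' Positions are projected to a local plane (km) about the segment centroid;
#' the per-axis semivariance is averaged over all fix pairs whose lag falls in
#' a bin. For regular data the bins default to the exact multiples of the grid
#' interval.
#'
#' @param segment A `month_segment` (from [split_months()]) or any track-like
#'   data.frame with `timestamp`, `lon`, `lat` (and optionally `observed`).
#' @param lag_bins Optional numeric vector of bin break points (hours);
#'   default: one bin per distinct lag.
#' @param min_fixes Minimum non-missing fixes (default 8).
#' @return An `empirical_svf` object: `data.frame(lag_h, svf_km2, n_pairs)`
#'   with attribute `centre` (projection centre lon/lat).
#' @export
empirical_svf <- function(segment, lag_bins = NULL, min_fixes = 8) {
  obs <- if ("observed" %in% names(segment)) segment[segment$observed, , drop = FALSE]
         else segment
  if (nrow(obs) < min_fixes)
    stop(structure(class = c("movresid_unusable", "error", "condition"),
                   list(message = sprintf("only %d non-missing fixes (< %d)",
                                          nrow(obs), min_fixes),
                        call = sys.call())))
  centre <- c(mean(obs$lon), mean(obs$lat))
  xy <- project_aeqd(obs$lon, obs$lat, centre)
  th <- as.numeric(obs$timestamp) / 3600
  n <- nrow(obs)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lag <- th[ij[, 2]] - th[ij[, 1]]
  sq <- (xy[ij[, 2], 1] - xy[ij[, 1], 1])^2 + (xy[ij[, 2], 2] - xy[ij[, 1], 2])^2
  if (is.null(lag_bins)) {
    key <- round(lag, 6)
  } else {
    key <- lag_bins[findInterval(lag, lag_bins)]
  }
  agg_n <- tapply(sq, key, length)
  agg_m <- tapply(sq, key, mean)
  out <- data.frame(lag_h = as.numeric(names(agg_m)),
                    svf_km2 = as.numeric(agg_m) / 4,  # /(2*d), d = 2
                    n_pairs = as.integer(agg_n))
  out <- out[order(out$lag_h), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "centre") <- centre
  class(out) <- c("empirical_svf", "data.frame")
  out
}

#' Fit the OUF model to an empirical semivariance function
#'
#' Weighted least squares of [ouf_svf()] against the empirical SVF, weights
#' proportional to pair counts, minimised over log-parameters
#' `(log sigma2, log tau_v, log(tau_p - tau_v))` from a deterministic
#' multi-start grid (`tau_p` in {6, 24, 96, 384} h x `tau_v` in
#' {0.25, 1, 4} h). `sigma2` is bounded above at 100x the largest empirical
#' semivariance; a fit pinned to that bound (diffusive/ballistic data) is
#' flagged non-converged.
#'
#' @param svf An [empirical_svf()] (>= 4 populated lag bins).
#' @param tau_p_starts,tau_v_starts Multi-start grids (hours).
#' @return An `ouf_fit` list: `sigma2_hat`, `tau_p_hat`, `tau_v_hat`,
#'   `objective`, `converged`, `sigma2_at_bound`, `n_starts_ok`.
#' @export
fit_ouf <- function(svf, tau_p_starts = c(6, 24, 96, 384),
                    tau_v_starts = c(0.25, 1, 4)) {
  svf <- svf[svf$lag_h > 0 & is.finite(svf$svf_km2), , drop = FALSE]
  if (nrow(svf) < 4) {
    return(structure(list(sigma2_hat = NA_real_, tau_p_hat = NA_real_,
                          tau_v_hat = NA_real_, objective = NA_real_,
                          converged = FALSE, sigma2_at_bound = FALSE,
                          n_starts_ok = 0L, reason = "fewer than 4 lag bins"),
                     class = "ouf_fit"))
  }
  w <- svf$n_pairs / sum(svf$n_pairs)
  gmax <- max(svf$svf_km2)
  if (gmax <= 1e-12) {  # stationary segment: zero variance everywhere
    return(structure(list(sigma2_hat = 0, tau_p_hat = min(svf$lag_h),
                          tau_v_hat = min(svf$lag_h) / 2, objective = 0,
                          converged = TRUE, sigma2_at_bound = FALSE,
                          n_starts_ok = 0L, reason = "stationary"),
                     class = "ouf_fit"))
  }
  ub_s2 <- 100 * gmax
  obj <- function(par) {
    s2 <- exp(par[1]); tv <- exp(par[2]); tp <- tv + exp(par[3])
    g <- ouf_svf(svf$lag_h, s2, tp, tv)
    sum(w * (svf$svf_km2 - g)^2)
  }
  lower <- c(log(1e-9), log(1e-3), log(1e-4))
  upper <- c(log(ub_s2), log(1e5), log(1e7))
  s2_0 <- stats::median(svf$svf_km2[svf$lag_h >= stats::quantile(svf$lag_h, 0.5)])
  s2_0 <- min(max(s2_0, 1e-6), ub_s2)
  best <- NULL; n_ok <- 0L
  for (tp0 in tau_p_starts) for (tv0 in tau_v_starts) {
    if (tp0 <= tv0) next
    par0 <- pmin(pmax(c(log(s2_0), log(tv0), log(tp0 - tv0)), lower), upper)
    res <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(structure(list(sigma2_hat = NA_real_, tau_p_hat = NA_real_,
                          tau_v_hat = NA_real_, objective = NA_real_,
                          converged = FALSE, sigma2_at_bound = FALSE,
                          n_starts_ok = 0L, reason = "all starts failed"),
                     class = "ouf_fit"))
  }
  # polish the winning start (L-BFGS-B occasionally reports an abnormal
  # line-search exit at an already-optimal point); clamp back into bounds
  pol <- tryCatch(stats::optim(best$par, function(p)
    obj(pmin(pmax(p, lower), upper)), method = "Nelder-Mead",
    control = list(maxit = 1000)), error = function(e) NULL)
  ok <- best$convergence == 0
  if (!is.null(pol) && pol$value <= best$value) {
    best <- list(par = pmin(pmax(pol$par, lower), upper), value = pol$value,
                 convergence = pol$convergence)
    ok <- pol$convergence == 0
  }
  s2 <- exp(best$par[1]); tv <- exp(best$par[2]); tp <- tv + exp(best$par[3])
  at_bound <- (log(ub_s2) - best$par[1]) < 1e-6
  structure(list(sigma2_hat = s2, tau_p_hat = tp, tau_v_hat = tv,
                 objective = best$value,
                 converged = ok && !at_bound,
                 sigma2_at_bound = at_bound, n_starts_ok = n_ok,
                 reason = if (at_bound) "sigma2 at upper bound" else NA_character_),
            class = "ouf_fit")
}

#' Asymptote check: is the fitted variogram flat within the month?
#'
#' Evaluates three scale-free diagnostics of the fitted OUF semivariance at
#' the check lag `T` (default half the month window):
#' `d1 = gamma'(T) * T / sigma2_hat`, `d2 = |gamma''(T)| * T^2 / sigma2_hat`,
#' and the relative gap to the asymptote `gap = 1 - gamma(T) / sigma2_hat`.
#' The month is called resident when the fit converged and all three are at
#' or below their tolerances. The gap criterion is what separates
#' long-memory (non-resident) fits: for `tau_p >> T` the first-derivative
#' criterion `x e^{-x}` (x = T/tau_p) is small on both sides of the asymptote
#' and cannot discriminate.
#'
#' @param fit An [fit_ouf()] result.
#' @param window_h Month span in hours (e.g. 720 for a 30-day month).
#' @param check_lag_h Check lag `T`; default `window_h / 2`.
#' @param eps1,eps2,eps_gap Tolerances for `d1`, `d2`, `gap` (defaults 0.05).
#' @param bird_id,year,month,n_fixes Carried into the call record.
#' @return A one-row `data.frame` (a residency call): identification columns,
#'   `resident`, `usable`, the three diagnostics, the fitted parameters, the
#'   tolerances and a `reason` string.
#' @export
asymptote_check <- function(fit, window_h, check_lag_h = window_h / 2,
                            eps1 = 0.05, eps2 = 0.05, eps_gap = 0.05,
                            bird_id = NA_character_, year = NA_integer_,
                            month = NA_integer_, n_fixes = NA_integer_) {
  base <- data.frame(bird_id = bird_id, year = year, month = month,
                     n_fixes = n_fixes, usable = TRUE, resident = FALSE,
                     sigma2_hat = fit$sigma2_hat, tau_p_hat = fit$tau_p_hat,
                     tau_v_hat = fit$tau_v_hat, converged = fit$converged,
                     d1 = NA_real_, d2 = NA_real_, gap = NA_real_,
                     check_lag_h = check_lag_h, eps1 = eps1, eps2 = eps2,
                     eps_gap = eps_gap, reason = NA_character_,
                     stringsAsFactors = FALSE)
  if (!isTRUE(fit$converged)) {
    base$reason <- paste0("fit not converged",
                          if (!is.na(fit$reason %||% NA)) paste0(": ", fit$reason) else "")
    return(base)
  }
  if (fit$sigma2_hat <= 1e-12) {  # stationary: trivially at asymptote
    base$resident <- TRUE
    base$d1 <- base$d2 <- base$gap <- 0
    base$reason <- "stationary"
    return(base)
  }
  Tlag <- check_lag_h
  s2 <- fit$sigma2_hat; tp <- fit$tau_p_hat; tv <- fit$tau_v_hat
  base$d1 <- ouf_svf_d1(Tlag, s2, tp, tv) * Tlag / s2
  base$d2 <- abs(ouf_svf_d2(Tlag, s2, tp, tv)) * Tlag^2 / s2
  base$gap <- 1 - ouf_svf(Tlag, s2, tp, tv) / s2
  base$resident <- base$d1 <= eps1 && base$d2 <= eps2 && base$gap <= eps_gap
  base
}

#' Classify every bird-month as resident, non-resident, or unusable
#'
#' Full monthly pipeline: regularize each track onto the common grid, split
#' into local calendar months, estimate the empirical SVF, fit the OUF model,
#' and run the asymptote check. Months with fewer than `min_fixes` usable
#' fixes are recorded as unusable (excluded from odds denominators), never as
#' non-resident.
#'
#' @param tracks A list of track data.frames (or a single track).
#' @param grid_interval_h,tolerance_min Passed to [regularize()].
#' @param min_fixes Minimum observed fixes per month (default 20).
#' @param eps1,eps2,eps_gap Passed to [asymptote_check()].
#' @return A `data.frame` of residency calls, one row per bird-month.
#' @export
classify_all_months <- function(tracks, grid_interval_h = 6, tolerance_min = 90,
                                min_fixes = 20, eps1 = 0.05, eps2 = 0.05,
                                eps_gap = 0.05) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  rows <- list()
  for (trk in tracks) {
    rt <- regularize(trk, grid_interval_h, tolerance_min)
    for (seg in split_months(rt)) {
      nfix <- attr(seg, "n_fixes")
      id <- list(bird_id = seg$bird_id[1], year = attr(seg, "year"),
                 month = attr(seg, "month"), n_fixes = nfix)
      if (nfix < min_fixes) {
        rows[[length(rows) + 1]] <- data.frame(
          bird_id = id$bird_id, year = id$year, month = id$month,
          n_fixes = nfix, usable = FALSE, resident = NA,
          sigma2_hat = NA_real_, tau_p_hat = NA_real_, tau_v_hat = NA_real_,
          converged = NA, d1 = NA_real_, d2 = NA_real_, gap = NA_real_,
          check_lag_h = NA_real_, eps1 = eps1, eps2 = eps2, eps_gap = eps_gap,
          reason = "too few fixes", stringsAsFactors = FALSE)
        next
      }
      svf <- empirical_svf(seg)
      fit <- fit_ouf(svf)
      rows[[length(rows) + 1]] <- asymptote_check(
        fit, window_h = attr(seg, "window_h"), eps1 = eps1, eps2 = eps2,
        eps_gap = eps_gap, bird_id = id$bird_id, year = id$year,
        month = id$month, n_fixes = nfix)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
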
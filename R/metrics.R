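# Distance statistics per bird-day and permutation comparisons between groups.
# All distances are great-circle km; days, midnights and seasons are local
# (timestamp + utc_offset_h).

.local_time <- function(track) track$timestamp + (track$utc_offset_h %||% 0) * 3600

#' Daily movement metrics
#'
#' For every local day, computes the cumulative distance moved
#' (`cumulative_km`, sum of step lengths starting in that day), the maximum
#' distance from that day's roost (`max_from_roost_km`), and the roost-shift
#' distance from the previous day's midnight fix (`roost_shift_km`). The roost
#' is the raw fix nearest local midnight within +/- 3 h; days without such a
#' fix get `NA` roost metrics but keep their cumulative distance.
#'
#' @param track A track data.frame with >= 2 fixes.
#' @param midnight_tol_h Half-window for the midnight fix (hours).
#' @return `data.frame(bird_id, date, cumulative_km, max_from_roost_km,
#'   roost_shift_km, n_fixes)`.
#' @export
daily_metrics <- function(track, midnight_tol_h = 3) {
  .validate_track(track)
  if (nrow(track) < 2) stop("track must have >= 2 fixes")
  lt <- .local_time(track)
  d <- as.Date(format(lt, "%Y-%m-%d"))
  n <- nrow(track)
  steps <- haversine_km(track$lon[-n], track$lat[-n], track$lon[-1], track$lat[-1])
  step_day <- d[-n]                                  # step belongs to its start day
  days <- sort(unique(d))
  cum <- vapply(days, function(dd) sum(steps[step_day == dd]), 0)
  # roost fix: nearest local midnight (start of day) within tolerance
  midnight <- as.POSIXct(paste(days, "00:00:00"), tz = "UTC")
  lt_num <- as.numeric(lt)
  roost_idx <- vapply(midnight, function(m) {
    dt <- abs(lt_num - as.numeric(m))
    i <- which.min(dt)
    if (dt[i] <= midnight_tol_h * 3600) i else NA_integer_
  }, 0L)
  maxd <- shift <- rep(NA_real_, length(days))
  for (k in seq_along(days)) {
    ri <- roost_idx[k]
    if (is.na(ri)) next
    in_day <- which(d == days[k])
    maxd[k] <- max(haversine_km(track$lon[ri], track$lat[ri],
                                track$lon[in_day], track$lat[in_day]))
    if (k > 1 && !is.na(roost_idx[k - 1])) {
      pi_ <- roost_idx[k - 1]
      shift[k] <- haversine_km(track$lon[pi_], track$lat[pi_],
                               track$lon[ri], track$lat[ri])
    }
  }
  data.frame(bird_id = track$bird_id[1], date = days, cumulative_km = cum,
             max_from_roost_km = maxd, roost_shift_km = shift,
             n_fixes = as.integer(table(d)[as.character(days)]),
             stringsAsFactors = FALSE)
}

#' Cumulative travel rates per hour, per day, and per year
#'
#' Hourly series: distance summed over steps starting within each local clock
#' hour. Daily series: as [daily_metrics()], with a `partial` flag for days
#' whose coverage has gaps (first fix > 3 h after local midnight, last fix
#' before 21:00, or any internal gap > 6 h -- those days sum only observed
#' steps). The annual total is reported only when >= 365 distinct local days
#' carry data after exclusions; otherwise it is flagged incomplete.
#'
#' @param track A track data.frame.
#' @return A list with `hourly` (`data.frame(hour_start, km)`), `daily`
#'   (`data.frame(date, km, partial)`), `annual_km`, `n_days`, and
#'   `annual_complete`.
#' @export
cumulative_rates <- function(track) {
  .validate_track(track)
  lt <- .local_time(track)
  n <- nrow(track)
  steps <- haversine_km(track$lon[-n], track$lat[-n], track$lon[-1], track$lat[-1])
  hour_start <- as.POSIXct(format(lt[-n], "%Y-%m-%d %H:00:00"), tz = "UTC")
  hourly <- stats::aggregate(list(km = steps), list(hour_start = hour_start), sum)
  d <- as.Date(format(lt, "%Y-%m-%d"))
  days <- sort(unique(d))
  secs <- as.numeric(lt) - as.numeric(as.POSIXct(paste(d, "00:00:00"), tz = "UTC"))
  partial <- vapply(days, function(dd) {
    s <- sort(secs[d == dd])
    s[1] > 3 * 3600 || s[length(s)] < 21 * 3600 ||
      (length(s) > 1 && max(diff(s)) > 6 * 3600 + 1)
  }, TRUE)
  km <- vapply(days, function(dd) sum(steps[d[-n] == dd]), 0)
  daily <- data.frame(date = days, km = km, partial = partial)
  n_days <- length(days)
  list(hourly = hourly, daily = daily,
       annual_km = if (n_days >= 365) sum(km) else NA_real_,
       n_days = n_days, annual_complete = n_days >= 365)
}

.pctl_stat <- function(statistic) {
  switch(statistic,
         median = function(x) stats::median(x),
         p10 = function(x) unname(stats::quantile(x, 0.10, type = 7)),
         p80 = function(x) unname(stats::quantile(x, 0.80, type = 7)),
         stop("statistic must be one of 'median', 'p10', 'p80'"))
}

#' Monthly percentile summary of a metric
#'
#' Median, 10th and 80th percentiles per calendar month (and optional group),
#' using linear interpolation between order statistics (quantile type 7).
#'
#' @param values Numeric metric values.
#' @param month Integer months (1..12) aligned with `values`.
#' @param group Optional grouping vector.
#' @return `data.frame(group, month, n, median, p10, p80)`; empty groups are
#'   omitted.
#' @export
monthly_summary <- function(values, month, group = NULL) {
  if (is.null(group)) group <- "all"
  keep <- !is.na(values)
  df <- data.frame(values = values[keep], month = month[keep],
                   group = rep_len(group, length(values))[keep])
  out <- do.call(rbind, lapply(split(df, list(df$group, df$month), drop = TRUE),
    function(g) data.frame(group = g$group[1], month = g$month[1],
                           n = nrow(g),
                           median = stats::median(g$values),
                           p10 = unname(stats::quantile(g$values, .10, type = 7)),
                           p80 = unname(stats::quantile(g$values, .80, type = 7)))))
  out <- out[order(out$group, out$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-group permutation test on a percentile statistic
#'
#' Two-sided label-permutation test of the difference in a percentile
#' statistic (median, 10th or 80th percentile) between two groups, with the
#' +1-corrected p-value `p = (1 + #(|D_perm| >= |D_obs|)) / (1 + n_perm)`.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param statistic `"median"`, `"p10"` or `"p80"`.
#' @param n_perm Number of label permutations (>= 1), default 1000.
#' @param seed Integer RNG seed or `NULL`.
#' @return A list with `p_value`, `observed` (signed difference a - b),
#'   `statistic`, `n_perm`.
#' @export
percentile_permutation_test <- function(a, b, statistic = "median",
                                        n_perm = 1000, seed = NULL) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  if (n_perm < 1) stop("n_perm must be >= 1")
  fn <- .pctl_stat(statistic)
  if (!is.null(seed)) set.seed(seed)
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  obs <- fn(a) - fn(b)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    if (abs(fn(pool[idx]) - fn(pool[-idx])) >= abs(obs) - 1e-12) cnt <- cnt + 1L
  }
  list(p_value = (1 + cnt) / (1 + n_perm), observed = obs,
       statistic = statistic, n_perm = n_perm)
}

#' Pairwise percentile permutation tests with multiplicity adjustment
#'
#' All unordered pairs of groups are tested with
#' [percentile_permutation_test()] and the p-values adjusted (Holm step-down
#' by default).
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param statistic,n_perm,seed As in [percentile_permutation_test()].
#' @param adjust Method passed to [stats::p.adjust()].
#' @return A symmetric matrix of adjusted p-values (`NA` diagonal); attribute
#'   `"raw"` holds the unadjusted matrix.
#' @export
pairwise_percentile_tests <- function(groups, statistic = "median",
                                      n_perm = 1000, seed = NULL,
                                      adjust = "holm") {
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  if (!is.null(seed)) set.seed(seed)
  pairs <- utils::combn(k, 2)
  raw <- apply(pairs, 2, function(ij)
    percentile_permutation_test(groups[[ij[1]]], groups[[ij[2]]], statistic,
                                n_perm, seed = NULL)$p_value)
  adj <- stats::p.adjust(raw, method = adjust)
  m_raw <- m_adj <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    m_raw[i1, i2] <- m_raw[i2, i1] <- raw[j]
    m_adj[i1, i2] <- m_adj[i2, i1] <- adj[j]
  }
  structure(m_adj, raw = m_raw)
}
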
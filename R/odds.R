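# Residency frequency summaries: odds with delta-method CIs, percentages by
# group, and seasonal two-proportion permutation tests. Unusable months (too
# few fixes) are excluded from both numerator and denominator throughout.

#' Odds of residency with a delta-method confidence interval
#'
#' `p_hat = n_res / n`, `odds = p_hat / (1 - p_hat)`; the standard error is
#' computed on the proportion, `SE(p_hat) = sqrt(p_hat (1 - p_hat) / n)`, and
#' mapped to the odds scale via the delta method,
#' `SE(odds) = SE(p_hat) / (1 - p_hat)^2`; `CI = odds +/- z * SE(odds)`,
#' floored at 0. With no non-resident months the odds are infinite and the CI
#' undefined (flagged).
#'
#' @param n_res,n_nonres Counts of resident / non-resident classified months
#'   (`n_res + n_nonres >= 1`).
#' @param z Normal quantile for the CI (default 1.96).
#' @return `data.frame(odds, ci_low, ci_high, p_hat, n, defined)`.
#' @examples
#' monthly_odds(66, 33) # odds = 2
#' @export
monthly_odds <- function(n_res, n_nonres, z = 1.96) {
  if (n_res < 0 || n_nonres < 0 || n_res + n_nonres < 1)
    stop("need non-negative counts with n_res + n_nonres >= 1")
  n <- n_res + n_nonres
  p_hat <- n_res / n
  if (n_nonres == 0) {
    return(data.frame(odds = Inf, ci_low = NA_real_, ci_high = NA_real_,
                      p_hat = p_hat, n = n, defined = FALSE))
  }
  odds <- n_res / n_nonres     # = p_hat / (1 - p_hat), exact in counts
  se_p <- sqrt(p_hat * (1 - p_hat) / n)
  se_odds <- se_p / (1 - p_hat)^2
  data.frame(odds = odds, ci_low = max(odds - z * se_odds, 0),
             ci_high = odds + z * se_odds, p_hat = p_hat, n = n,
             defined = TRUE)
}

#' Per-calendar-month odds of residency from a calls table
#'
#' @param calls Residency calls (from [classify_all_months()]); unusable
#'   months are dropped.
#' @param z CI normal quantile.
#' @return One row per calendar month present: `month`, counts, and the
#'   [monthly_odds()] columns.
#' @export
odds_by_calendar_month <- function(calls, z = 1.96) {
  u <- calls[!is.na(calls$resident), , drop = FALSE]
  out <- do.call(rbind, lapply(sort(unique(u$month)), function(m) {
    g <- u[u$month == m, , drop = FALSE]
    cbind(data.frame(month = m, n_res = sum(g$resident),
                     n_nonres = sum(!g$resident)),
          monthly_odds(sum(g$resident), sum(!g$resident), z))
  }))
  rownames(out) <- NULL
  out
}

#' Percentage of months classified resident, by group
#'
#' `100 * n_res / (n_res + n_nonres)` per group over usable months only;
#' groups with no usable months are omitted. Rounding to integers is applied
#' only at presentation (`round_pct`).
#'
#' @param calls Residency calls table.
#' @param by Character vector of grouping columns present in `calls` (or a
#'   vector/data.frame of group labels aligned with rows).
#' @param round_pct Round the reported percentage to integers (default
#'   `TRUE`, matching tabular presentation).
#' @return `data.frame(group, n_res, n_months, pct_resident)`.
#' @export
residency_percentages <- function(calls, by = NULL, round_pct = TRUE) {
  u <- calls[!is.na(calls$resident), , drop = FALSE]
  if (nrow(u) == 0) return(data.frame(group = character(), n_res = integer(),
                                      n_months = integer(),
                                      pct_resident = numeric()))
  grp <- if (is.null(by)) rep("all", nrow(u))
         else if (is.character(by) && all(by %in% names(u)))
           do.call(paste, c(u[by], sep = ":"))
         else rep_len(by, nrow(u))
  sp <- split(u$resident, grp)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    pct <- 100 * sum(sp[[g]]) / length(sp[[g]])
    data.frame(group = g, n_res = sum(sp[[g]]), n_months = length(sp[[g]]),
               pct_resident = if (round_pct) round(pct) else pct,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample permutation test for a difference in seasonal residency proportions
#'
#' Pools the month-level resident/non-resident outcomes of two seasons,
#' permutes the season labels, and compares the observed difference in
#' proportions `p_A - p_B` against the permutation null (two-sided, +1
#' corrected). Month-level exchangeability is assumed (within-bird
#' correlation is ignored, as in the classical two-proportion permutation
#' test).
#'
#' @param calls Residency calls table (needs `month` and `resident`).
#' @param seasonA,seasonB Season names (`"summer"`, `"autumn"`, `"winter"`,
#'   `"spring"`).
#' @param n_perm Permutations, default 1000.
#' @param seed Integer RNG seed or `NULL`.
#' @return A list with `delta_prop` (`p_A - p_B`), `p_value`, `n_A`, `n_B`.
#' @export
seasonal_proportion_test <- function(calls, seasonA, seasonB, n_perm = 1000,
                                     seed = NULL) {
  u <- calls[!is.na(calls$resident), , drop = FALSE]
  s <- season_of(u$month)
  a <- u$resident[s == seasonA]
  b <- u$resident[s == seasonB]
  if (length(a) < 1 || length(b) < 1)
    stop("both seasons need >= 1 usable month")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= abs(obs) - 1e-12)
      cnt <- cnt + 1L
  }
  list(delta_prop = obs, p_value = (1 + cnt) / (1 + n_perm),
       n_A = na, n_B = length(b))
}
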
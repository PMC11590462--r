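# movresid

Movement strategies and residency analysis for GPS-tracked waterbirds.

Ibis, spoonbills and other aggregate-nesting waterbirds move across a
spectrum from tight residency to continent-scale nomadism, and managers who
allocate environmental water need to know **where and when birds are
resident**. `movresid` implements a month-granular, variogram-based
residency pipeline for GPS telemetry, together with the distance statistics,
overlap analysis, odds summaries and site-revisitation statistics that
surround it — and a synthetic-track generator with known ground truth so the
entire pipeline can be validated end to end.

## The model at the core

Range-resident movement is modelled per axis as the
Ornstein–Uhlenbeck–Foraging (OUF) process with stationary variance σ²
(km²), positional decorrelation timescale τ_p and velocity timescale τ_v
(hours, τ_p > τ_v). Its semivariance function (SVF) is

    γ(τ) = σ² [ 1 − (τ_p e^{−τ/τ_p} − τ_v e^{−τ/τ_v}) / (τ_p − τ_v) ]

which rises from 0 and flattens to the asymptote σ². The pipeline:

1. place each bird on a common 6-hourly grid (`regularize`), split by local
   calendar month (`split_months`);
2. estimate the empirical per-axis SVF (`empirical_svf`) and fit the OUF
   model by weighted least squares (`fit_ouf`);
3. call a month *resident* when the fitted SVF has reached its asymptote
   within the month — scale-free first/second-derivative and asymptote-gap
   checks (`asymptote_check`, `classify_all_months`);
4. estimate each resident month's utilisation distribution with
   autocorrelated kernel density estimation (`akde_ud`, bandwidth driven by
   the effective sample size N_eff = span/τ_p) and its 95% contour area
   (`contour_area`);
5. merge consecutive resident months whose UDs overlap (Bhattacharyya
   coefficient, parametric-bootstrap CI, merge when the lower bound
   exceeds 0.01) into residency *blocks* (`merge_blocks`);
6. summarise residency frequency as per-calendar-month odds with
   delta-method CIs (`monthly_odds`) and seasonal two-proportion permutation
   tests (`seasonal_proportion_test`);
7. compute visitation statistics of tracks against residency polygons and
   classify areas against user-supplied wetland layers (`detect_visits`,
   `classify_areas`).

All distribution comparisons use label-permutation tests on medians and
percentiles (`percentile_permutation_test`, Holm-adjusted pairwise matrix).

## Worked example

Simulate a bird that is resident (σ² = 100 km², τ_p = 24 h) for
January–March, nomadic for April–May, then resident again June–July, and
run the classifier:

```r
library(movresid)

rseg <- function(s, e) list(start = s, end = e, mode = "resident",
                            params = list(sigma2 = 100, tau_p = 24, tau_v = 1))
nseg <- function(s, e) list(start = s, end = e, mode = "nomadic",
                            params = list(speed_kmh = 15, heading_persistence = 0.95))
sch <- mode_schedule(list(rseg("2021-01-01", "2021-04-01"),
                          nseg("2021-04-01", "2021-06-01"),
                          rseg("2021-06-01", "2021-08-01")))
sim <- simulate_mixed_track(sch, seed = 42, bird_id = "SNI_042")
calls <- classify_all_months(sim$track)
calls[, c("bird_id", "year", "month", "n_fixes", "resident", "gap", "tau_p_hat")]
#>   bird_id year month n_fixes resident          gap   tau_p_hat
#> 1 SNI_042 2021     1     123     TRUE 5.146458e-04    49.12803
#> 2 SNI_042 2021     2     112     TRUE 7.255755e-06    28.39336
#> 3 SNI_042 2021     3     124     TRUE 1.043523e-08    20.24145
#> 4 SNI_042 2021     4     120    FALSE           NA 26428.56289
#> 5 SNI_042 2021     5     124    FALSE 3.288131e-01   161.13360
#> 6 SNI_042 2021     6     120     TRUE 6.562863e-09    18.99845
#> 7 SNI_042 2021     7     124     TRUE 1.109786e-07    23.12728
#> 8 SNI_042 2021     8       2       NA           NA          NA
```

Every usable month matches the schedule's truth labels (`sim$labels`): the
resident months recover τ_p near the simulated 24 h with a tiny asymptote
gap, the April fit has τ_p ≫ the month window (no asymptote, `gap = NA`
because the fit ran into its σ² bound and is non-converged), May converges
but sits far from its asymptote (gap 0.33 > 0.05), and August has only 2
fixes so it is unusable rather than non-resident.

Merging overlapping consecutive months and summarising:

```r
blocks <- merge_blocks(sim$track, calls = calls, seed = 1)
blocks
#>   bird_id block_id start_month end_month n_months n_fixes area95_km2
#> 1 SNI_042        1     2021-01   2021-03        3     359   1667.919
#> 2 SNI_042        2     2021-06   2021-07        2     244   1471.510

monthly_odds(sum(calls$resident, na.rm = TRUE), sum(!calls$resident, na.rm = TRUE))
#>   odds ci_low  ci_high     p_hat n defined
#> 1  2.5      0 6.599634 0.7142857 7    TRUE
```

The two residency spells become two blocks (the nomadic gap prevents
merging), each with a joint 95% AKDE area close to the Gaussian expectation
5.991·π·σ² ≈ 1882 km². The bird was resident in 5 of 7 classified months:
odds 2.5, with a wide delta-method CI at n = 7.

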
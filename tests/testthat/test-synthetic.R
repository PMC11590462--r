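# synthetic track generators: exactness, determinism, constructed truths

test_that("sim_config validates its invariants", {
  expect_error(sim_config(-1, 24, 1), "sigma2")
  expect_error(sim_config(100, 1, 24), "tau_p > tau_v")
  expect_error(sim_config(100, 24, 1, fix_interval_h = 0), "fix_interval_h")
  expect_error(sim_config(100, 24, 1, fix_interval_h = 24, duration_days = 1),
               "two fix intervals")
})

test_that("zero-variance OUF track sits at the centre; same seed is bit-identical", {
  cfg <- sim_config(0, 24, 1, 6, 10, centre = c(145, -35), seed = 4)
  trk <- simulate_ouf_track(cfg)
  expect_equal(trk$lon, rep(145, nrow(trk)))
  expect_equal(trk$lat, rep(-35, nrow(trk)))

  cfg2 <- sim_config(100, 24, 1, 6, 30, seed = 11)
  expect_identical(simulate_ouf_track(cfg2), simulate_ouf_track(cfg2))
})

test_that("OUF sample variance and SVF match the stationary law (Monte Carlo)", {
  # scaled-down replicate count here; the acceptance suite runs 200
  set.seed(101)
  g24_oracle <- 100 * (1 - (24 * exp(-1) - 1 * exp(-24)) / (24 - 1)) # 61.61 km2
  reps <- 40
  v <- g <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(100, 24, 1, 6, 30)
    trk <- simulate_ouf_track(cfg)
    xy <- project_aeqd(trk$lon, trk$lat, cfg$centre)
    v[r] <- mean(apply(xy, 2, stats::var))
    s <- empirical_svf(trk)
    g[r] <- s$svf_km2[s$lag_h == 24]
  }
  expect_lt(abs(mean(v) / 100 - 1), 0.15)
  expect_lt(abs(mean(g) / g24_oracle - 1), 0.10)
})

test_that("positions at widely separated times are stationary N(centre, sigma2 I)", {
  cfg <- sim_config(100, 24, 1, fix_interval_h = 240, duration_days = 5000,
                    seed = 21)
  trk <- simulate_ouf_track(cfg)
  xy <- project_aeqd(trk$lon, trk$lat, cfg$centre)
  expect_gt(nrow(xy), 499)
  expect_gt(stats::ks.test(xy[, 1], "pnorm", 0, 10)$p.value, 0.01)
  expect_gt(stats::ks.test(xy[, 2], "pnorm", 0, 10)$p.value, 0.01)
})

test_that("velocity autocorrelation decays on the tau_v timescale", {
  cfg <- sim_config(100, 200, 4, fix_interval_h = 0.25, duration_days = 120,
                    seed = 23)
  trk <- simulate_ouf_track(cfg)
  xy <- project_aeqd(trk$lon, trk$lat, cfg$centre)
  slopes <- vapply(1:2, function(ax) {
    vel <- diff(xy[, ax]) / 0.25
    lags <- 1:8
    ac <- vapply(lags, function(L)
      stats::cov(vel[seq_len(length(vel) - L)], vel[-seq_len(L)]), 0)
    unname(stats::coef(stats::lm(log(ac) ~ I(lags * 0.25)))[2])
  }, 0)
  expect_lt(max(abs(slopes / (-1 / 4) - 1)), 0.20)
})

test_that("nomadic walk: validation, determinism, stationary and ballistic limits", {
  expect_error(simulate_nomadic_track(10, 1.2), "heading_persistence")
  expect_identical(simulate_nomadic_track(20, 0.9, 10, 6, seed = 5),
                   simulate_nomadic_track(20, 0.9, 10, 6, seed = 5))
  still <- simulate_nomadic_track(0, 0.9, 5, 6, seed = 6)
  expect_equal(stats::sd(still$lon), 0)
  expect_equal(stats::sd(still$lat), 0)
  # strongly persistent walk far exceeds 3x the 95% range of an OUF range
  nom <- simulate_nomadic_track(20, 0.99, 30, 6, seed = 4)
  xy <- project_aeqd(nom$lon, nom$lat, c(145, -35))
  net <- sqrt(sum(xy[nrow(xy), ]^2))
  ouf_range95 <- 2 * stats::qnorm(0.975) * sqrt(100) * sqrt(2)
  expect_gt(net, 3 * ouf_range95)
})

test_that("mode_schedule rejects gaps, overlaps and disorder", {
  seg <- function(s, e, m) list(start = s, end = e, mode = m,
                                params = list(sigma2 = 100, tau_p = 24, tau_v = 1,
                                              speed_kmh = 20))
  expect_error(mode_schedule(list(seg("2021-01-01", "2021-02-01", "resident"),
                                  seg("2021-03-01", "2021-04-01", "nomadic"))),
               "gap or overlap")
  expect_error(mode_schedule(list(seg("2021-02-01", "2021-03-01", "resident"),
                                  seg("2021-01-01", "2021-02-01", "nomadic"))),
               "ordered")
  expect_error(mode_schedule(list(seg("2021-01-01", "2021-02-01", "walkabout"))),
               "mode")
})

test_that("mixed track echoes its schedule as monthly labels", {
  rseg <- function(s, e) list(start = s, end = e, mode = "resident",
                              params = list(sigma2 = 100, tau_p = 24, tau_v = 1))
  nseg <- function(s, e) list(start = s, end = e, mode = "nomadic",
                              params = list(speed_kmh = 20, heading_persistence = 0.9))
  sch <- mode_schedule(list(rseg("2021-01-01", "2021-04-01"),
                            nseg("2021-04-01", "2021-06-01")))
  out <- simulate_mixed_track(sch, seed = 7)
  expect_equal(out$labels$mode, c("resident", "resident", "resident",
                                  "nomadic", "nomadic"))
  expect_false(any(is.na(out$track$lon)))
  # position continuity at every mode boundary (consecutive-fix jump bounded)
  xy <- project_aeqd(out$track$lon, out$track$lat, c(145, -35))
  steps <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  expect_lt(max(steps), 200)

  # alternating monthly modes over 12 months: 6 resident labels
  m0 <- seq(as.Date("2021-01-01"), by = "month", length.out = 13)
  segs <- lapply(1:12, function(i)
    if (i %% 2 == 1) rseg(m0[i], m0[i + 1]) else nseg(m0[i], m0[i + 1]))
  out12 <- simulate_mixed_track(mode_schedule(segs), seed = 8)
  expect_equal(sum(out12$labels$mode == "resident"), 6)
})

test_that("single all-resident schedule reproduces simulate_ouf_track exactly", {
  sch <- mode_schedule(list(list(start = "2021-01-01", end = "2021-03-02",
                                 mode = "resident",
                                 params = list(sigma2 = 100, tau_p = 24, tau_v = 1))))
  mixed <- simulate_mixed_track(sch, seed = 9, bird_id = "sim1")
  cfg <- sim_config(100, 24, 1, 6, 60, seed = 9, bird_id = "sim1")
  expect_equal(mixed$track, simulate_ouf_track(cfg))
})

test_that("diel track carries its constructed daily truths", {
  trk <- simulate_diel_track(c(145, -35), 5, duration_days = 8,
                             fix_interval_h = 1, seed = 3, roost_shift_km = 2)
  truth <- attr(trk, "truth")
  expect_equal(truth$max_from_roost_km, rep(5, 8))
  expect_equal(truth$roost_shift_km[-1], rep(2, 7))
  dm <- daily_metrics(trk)
  expect_equal(dm$max_from_roost_km, rep(5, 8), tolerance = 1e-4)
  expect_equal(dm$roost_shift_km[-1], rep(2, 7), tolerance = 1e-4)

  flat <- simulate_diel_track(c(145, -35), 0, duration_days = 5,
                              fix_interval_h = 1, seed = 3)
  dmf <- daily_metrics(flat)
  expect_equal(dmf$max_from_roost_km, rep(0, 5), tolerance = 1e-9)
  expect_equal(dmf$cumulative_km, rep(0, 5), tolerance = 1e-9)
  expect_error(simulate_diel_track(c(145, -35), -1), "forage_distance_km")
})
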
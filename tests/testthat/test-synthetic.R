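# The synthetic world: analytic fields, advection, programmed behavior,
# determinism.

test_that("fields evaluate the analytic formulas on the nodes", {
  cfg <- synth_config(seed = 5)
  f <- gen_fields(cfg)
  # zonal current inside the band: 0.04 at the eastern edge, 0.11 at the
  # western edge, zero outside the tapered band
  i37 <- which(f$lat == 37.5)
  expect_equal(f$u_co[i37, which(f$lon == 250)], 0.04)
  expect_equal(f$u_co[i37, which(f$lon == 120)], 0.11)
  expect_equal(f$u_co[which(f$lat == 20), which(f$lon == 180)], 0)
  expect_true(all(f$v_co == 0))
  # zonal-mean current in 30-45N increases monotonically going west
  band <- f$lat >= 30 & f$lat <= 45
  zmean <- colMeans(f$u_co[band, ])
  expect_true(all(diff(zmean) < 0))            # lon ascending eastward
  # clockwise gyre: eastward Stokes on the north side, westward south,
  # southward on the east side
  expect_gt(f$u_sto[which(f$lat == 50), 10], 0)
  expect_lt(f$u_sto[which(f$lat == 25), 10], 0)
  expect_lt(f$v_sto[10, which(f$lon == 240)], 0)
})

test_that("the generated world is a pure function of config + seed", {
  cfg <- synth_config(seed = 123, n_drifters = 5, n_turtles = 4, n_days = 40)
  f1 <- gen_fields(cfg); f2 <- gen_fields(cfg)
  expect_identical(f1, f2)
  d1 <- gen_drifters(cfg, f1); d2 <- gen_drifters(cfg, f2)
  expect_identical(d1, d2)
  t1 <- gen_turtles(cfg, f1); t2 <- gen_turtles(cfg, f1)
  expect_identical(t1, t2)
  # a different seed changes the draw
  d3 <- gen_drifters(synth_config(seed = 124, n_drifters = 5, n_days = 40), f1)
  expect_false(identical(d1$tracks$lat, d3$tracks$lat))
})

test_that("passive noise-free drifters have identically zero DC-velocity", {
  cfg <- synth_config(seed = 9, n_drifters = 12, n_days = 100,
                      process_noise_std = 0, argos_noise_std = 0)
  f <- gen_fields(cfg)
  dr <- gen_drifters(cfg, f)
  tr <- match_fields(velocity_over_ground(dr$tracks), f)
  dc <- dc_velocity(tr, cfg$gamma_drifter)
  # only the field-gradient discretization term remains; on the smooth
  # analytic fields it is orders of magnitude below any behavioral signal
  expect_lt(max(abs(dc$u_dc), na.rm = TRUE), 2e-4)
  expect_lt(max(abs(dc$v_dc), na.rm = TRUE), 2e-4)
  # with gamma = 0 planted and no noise the drift is pure current-following
  cfg0 <- synth_config(seed = 9, n_drifters = 6, n_days = 60, gamma_drifter = 0,
                       process_noise_std = 0, argos_noise_std = 0)
  dr0 <- gen_drifters(cfg0, f)
  tr0 <- match_fields(velocity_over_ground(dr0$tracks), f)
  dc0 <- dc_velocity(tr0, 0)
  expect_lt(max(abs(dc0$u_dc), na.rm = TRUE), 2e-4)
})

test_that("process noise disperses DC-trajectories like a random walk", {
  cfg <- synth_config(seed = 13, n_drifters = 120, n_days = 200,
                      process_noise_std = 0.05, argos_noise_std = 0,
                      release_lat = c(30, 40), release_lon = c(170, 200))
  f <- gen_fields(cfg)
  dr <- gen_drifters(cfg, f)
  tr <- dc_trajectory(dc_velocity(match_fields(velocity_over_ground(dr$tracks), f),
                                  cfg$gamma_drifter))
  es <- ensemble_stats(tr, min_n = 20)
  # sqrt(t) scaling: std at 4T ~ 2x std at T (within sampling slack)
  ratio <- es$std_x[180] / es$std_x[45]
  expect_gt(ratio, 1.5); expect_lt(ratio, 2.6)
  # magnitude: per-day step std ~ 0.05 m/s * 86.4 -> sigma * sqrt(t)
  expect_equal(es$std_x[100], 0.05 * 86.4 * sqrt(100), tolerance = 0.25)
})

test_that("turtle truth tables are internally consistent", {
  cfg <- synth_config(seed = 17, n_turtles = 12, n_days = 150,
                      foraging_rw_std = 0, argos_noise_std = 0)
  f <- gen_fields(cfg)
  tt <- gen_turtles(cfg, f)
  expect_equal(sort(unique(tt$tracks$id)), sort(tt$individuals$id))
  # homing switches exactly when the imputed size crosses the trigger
  tru <- merge(tt$truth, tt$individuals, by = "id")
  homing <- tru$vs_u < 0
  gp <- growth_params()
  rel <- stats::aggregate(date ~ id, tt$truth, min)
  for (i in sample(nrow(tru), 200)) {
    row <- tru[i, ]
    t0 <- rel$date[rel$id == row$id]
    size <- scl_at(gp, row$release_scl, t0, row$date)
    expect_equal(unname(homing[i]), unname(size >= row$trigger_scl))
  }
  # release sizes within the configured range
  expect_true(all(tt$individuals$release_scl >= 30 &
                  tt$individuals$release_scl <= 45))
})

test_that("zero-noise turtles give back the planted swimming velocity", {
  # full-pipeline identity: the estimator measures the two-day average of
  # the daily swimming velocity (centered differencing of midnights); with
  # all noise off the recovered DC-velocity matches it to < 1e-3 m/s
  cfg <- synth_config(seed = 19, n_turtles = 8, n_days = 250,
                      foraging_rw_std = 0, argos_noise_std = 0)
  f <- gen_fields(cfg)
  tt <- gen_turtles(cfg, f)
  tr <- dc_velocity(match_fields(velocity_over_ground(tt$tracks), f),
                    cfg$gamma_turtle)
  m <- merge(tr, tt$truth, by = c("id", "date"))
  m <- m[order(m$id, m$date), ]
  for (ix in split(seq_len(nrow(m)), m$id)) {
    vs_u <- m$vs_u[ix]; vs_v <- m$vs_v[ix]
    avg_u <- (vs_u + c(NA, vs_u[-length(vs_u)])) / 2
    avg_v <- (vs_v + c(NA, vs_v[-length(vs_v)])) / 2
    ok <- !is.na(m$u_dc[ix]) & !is.na(avg_u)
    expect_lt(max(abs(m$u_dc[ix] - avg_u)[ok]), 1e-3)
    expect_lt(max(abs(m$v_dc[ix] - avg_v)[ok]), 1e-3)
  }
})

test_that("drifters exiting the basin are truncated, not teleported", {
  cfg <- synth_config(seed = 29, n_drifters = 40, n_days = 400,
                      release_lat = c(44, 46), release_lon = c(245, 249),
                      process_noise_std = 0.15)
  f <- gen_fields(cfg)
  dr <- gen_drifters(cfg, f)
  lens <- table(dr$tracks$id)
  expect_true(any(lens < 400))            # some exit early near the edge
  expect_true(all(dr$truth$lat_true >= 20 & dr$truth$lat_true <= 55))
  expect_true(all(dr$truth$lon_true >= 120 & dr$truth$lon_true <= 250))
})

test_that("gamma for turtles is unbiased when swim is independent of Stokes", {
  # the uncorrelatedness argument: white foraging noise, no seasonal sine,
  # triggers never fire -> swim velocity independent of V_sto by
  # construction; over replicates the mean bias stays within one
  # (per-replicate) OLS standard error
  res <- t(sapply(1:25, function(s) {
    cfg <- synth_config(seed = 100 + s, n_turtles = 8, n_days = 150,
                        seasonal_amplitude_km = 0, trigger_scl_mean = 1e6,
                        foraging_rw_std = 0.05)
    f <- gen_fields(cfg)
    tt <- gen_turtles(cfg, f)
    fit <- fit_leeway(match_fields(velocity_over_ground(tt$tracks), f))
    c(gamma = fit$gamma, se = fit$gamma_se)
  }))
  bias <- mean(res[, "gamma"]) - 0.28
  expect_lt(abs(bias), mean(res[, "se"]))
  # and within 3 standard errors of the replicate mean
  expect_lt(abs(bias), 3 * sd(res[, "gamma"]) / sqrt(nrow(res)))
})

test_that("swim-free turtles are statistically indistinguishable from drifters", {
  cfg <- synth_config(seed = 41, n_drifters = 40, n_turtles = 40, n_days = 200,
                      seasonal_amplitude_km = 0, trigger_scl_mean = 1e6,
                      gamma_turtle = 0.88, foraging_rw_std = 0.05,
                      process_noise_std = 0.05)
  f <- gen_fields(cfg)
  dr <- gen_drifters(cfg, f)
  tt <- gen_turtles(cfg, f)
  u_d <- dc_velocity(match_fields(velocity_over_ground(dr$tracks), f), 0.88)
  u_t <- dc_velocity(match_fields(velocity_over_ground(tt$tracks), f), 0.88)
  # daily DC-velocities are autocorrelated (two-day smoothing), so the
  # exchangeable sampling unit is the track: two-sample test on track means
  p1 <- t.test(tapply(u_d$u_dc, u_d$id, mean, na.rm = TRUE),
               tapply(u_t$u_dc, u_t$id, mean, na.rm = TRUE))$p.value
  p2 <- t.test(tapply(u_d$v_dc, u_d$id, mean, na.rm = TRUE),
               tapply(u_t$v_dc, u_t$id, mean, na.rm = TRUE))$p.value
  expect_gt(p1, 0.01)
  expect_gt(p2, 0.01)
})
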
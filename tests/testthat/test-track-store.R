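# Track ingestion, midnight interpolation and velocity over ground.

test_that("read_tracks ingests, unwraps and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,date,lat,lon",
               "a,2005-03-01,30.0,150.0",
               "a,2005-03-02,30.2,150.4",
               "a,2005-03-03,30.4,150.8"), path)
  tr <- read_tracks(path)
  expect_equal(nrow(tr), 3)
  expect_s3_class(tr$date, "Date")
  expect_equal(tr$lat, c(30.0, 30.2, 30.4))

  # antimeridian crossing unwraps continuously
  writeLines(c("id,date,lat,lon",
               "b,2005-03-01,35,179.9",
               "b,2005-03-02,35,-179.9"), path)
  tr <- read_tracks(path)
  expect_equal(tr$lon, c(179.9, 180.1))
  expect_equal(wrap_lon(tr$lon), c(179.9, -179.9))

  # interleaved ids keep their own order
  writeLines(c("id,date,lat,lon",
               "x,2005-03-01,30,150", "y,2005-03-01,31,151",
               "x,2005-03-02,30,150", "y,2005-03-02,31,151"), path)
  tr <- read_tracks(path)
  expect_equal(unique(tr$id), c("x", "y"))
  expect_equal(sum(tr$id == "x"), 2)

  # duplicate (id, date) errors naming the id
  writeLines(c("id,date,lat,lon",
               "dup,2005-03-01,30,150", "dup,2005-03-01,30,150"), path)
  expect_error(read_tracks(path), "dup")

  # malformed dates dropped with warning; missing positions dropped
  writeLines(c("id,date,lat,lon",
               "c,2005-03-01,30,150", "c,not-a-date,30,150",
               "c,2005-03-03,NA,150", "c,2005-03-04,30,151"), path)
  expect_warning(tr <- read_tracks(path), "malformed")
  expect_equal(nrow(tr), 2)
})

test_that("midnight interpolation is the midpoint of adjacent noon fixes", {
  tr <- make_track(lat = c(30.0, 30.2), lon = c(150.0, 150.4))
  m <- interpolate_midnight(tr)
  expect_equal(nrow(m), 1)
  expect_equal(m$lat, 30.1)
  expect_equal(m$lon, 150.2)
  expect_equal(m$date, tr$date[2])  # 0:00 of the second day

  # stationary track: midnights equal the positions
  tr <- make_track(lat = rep(30, 4), lon = rep(150, 4))
  m <- interpolate_midnight(tr)
  expect_equal(m$lat, rep(30, 3))
  # 3-day block yields exactly 2 midnights
  expect_equal(nrow(interpolate_midnight(make_track(lat = 1:3, lon = rep(150, 3)))), 2)
  # gaps split blocks: 3 days + 2 days -> 2 + 1 midnights
  tr <- make_track(lat = rep(30, 5), lon = rep(150, 5))
  tr$date[4:5] <- tr$date[4:5] + 10
  expect_equal(nrow(interpolate_midnight(tr)), 3)
})

test_that("velocity over ground matches the closed form and conventions", {
  # stationary -> exactly zero on interior days
  tr <- velocity_over_ground(make_track(lat = rep(30, 5), lon = rep(150, 5)))
  expect_equal(tr$vg_u[2:4], rep(0, 3))
  expect_true(all(is.na(tr$vg_u[c(1, 5)])))  # block ends undefined, not zero

  # 0.1 degree of longitude per day at 35N: 0.1*(pi/180)*R*cos(35deg)/86400
  tr <- make_track(lat = rep(35, 5), lon = 180 + 0.1 * (0:4))
  tr <- velocity_over_ground(tr)
  expected <- 0.1 * (pi / 180) * 6371000 * cos(35 * pi / 180) / 86400
  expect_equal(tr$vg_u[3], expected, tolerance = 1e-10)
  expect_equal(expected, 0.1054, tolerance = 1e-3)
  expect_equal(tr$vg_v[3], 0)

  # direct method defined on all but the last day
  td <- velocity_over_ground(make_track(lat = rep(35, 3), lon = c(180, 180.1, 180.2)),
                             method = "direct")
  expect_false(is.na(td$vg_u[1]))
  expect_true(is.na(td$vg_u[3]))
  expect_equal(td$vg_u[1], expected, tolerance = 1e-10)
})

test_that("constant-velocity lines are recovered exactly; reversal negates", {
  for (lat0 in c(0, 25, 42, 60)) {
    n <- 30
    a <- 0.02   # deg lat / day; keeps the band well under 1 degree
    b <- 0.15   # deg lon / day
    tr <- make_track(lat = lat0 + a * (0:(n - 1)), lon = 150 + b * (0:(n - 1)))
    tr <- velocity_over_ground(tr)
    v_expect <- a * m_per_deg_lat() / 86400
    inner <- 2:(n - 1)
    expect_equal(tr$vg_v[inner], rep(v_expect, length(inner)), tolerance = 1e-9)
    # zonal speed varies only through cos(lat) across a <1 degree band
    u_expect <- b * m_per_deg_lon(tr$lat[inner]) / 86400
    expect_equal(tr$vg_u[inner], u_expect, tolerance = 1e-6)
  }

  tr <- make_track(lat = 30 + cumsum(runif(10, -0.05, 0.05)),
                   lon = 150 + cumsum(runif(10, -0.1, 0.1)))
  fw <- velocity_over_ground(tr)
  rv <- tr; rv$lat <- rev(tr$lat); rv$lon <- rev(tr$lon)
  bw <- velocity_over_ground(rv)
  expect_equal(bw$vg_u[2:9], -rev(fw$vg_u[2:9]), tolerance = 1e-12)
  expect_equal(bw$vg_v[2:9], -rev(fw$vg_v[2:9]), tolerance = 1e-12)
})

test_that("Argos-like 1 km position noise gives ~1.64 cm/s velocity noise", {
  # Monte-Carlo oracle on noisy stationary positions. One-day position
  # differences propagate 1-km errors to sqrt(2)*1000/86400 ~ 1.64 cm/s per
  # component (the "order of 2 cm/s" figure); the midnight-midpoint variant
  # spans two days and halves the noise to sqrt(2)*1000/(2*86400).
  set.seed(42)
  n <- 20000
  tr <- make_track(lat = 35 + rnorm(n, 0, 1000) / m_per_deg_lat(),
                   lon = 180 + rnorm(n, 0, 1000) / m_per_deg_lon(35))
  td <- velocity_over_ground(tr, method = "direct")
  expect_equal(sd(td$vg_u, na.rm = TRUE), sqrt(2) * 1000 / 86400, tolerance = 0.05)
  expect_equal(sd(td$vg_v, na.rm = TRUE), sqrt(2) * 1000 / 86400, tolerance = 0.05)
  tm <- velocity_over_ground(tr)
  expect_equal(sd(tm$vg_u, na.rm = TRUE), sqrt(2) * 1000 / (2 * 86400), tolerance = 0.05)
})

test_that("longitude unwrap/wrap round-trips modulo 360", {
  set.seed(1)
  lon <- cumsum(runif(50, -3, 3)) + 175
  wrapped <- wrap_lon(lon)
  expect_equal((unwrap_lon(wrapped) - lon) %% 360, rep(0, 50), tolerance = 1e-12)
})
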
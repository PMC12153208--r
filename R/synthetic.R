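# Seedable synthetic ocean, drifters and behaviorally programmed turtles.
#
# The generator states a North Pacific-like world: a basin spanning
# 20-55 degN and 120 degE-110 degW (kept as continuous longitudes
# 120..250 degE), an eastward mean flow of 4-11 cm/s between 30 and 45 degN
# strengthening westward, and a clockwise surface Stokes-drift gyre of a few
# cm/s. Passive drifters obey V = V_co + gamma * V_sto + process noise;
# turtles add a programmed swimming velocity: a seasonal meridional sinusoid
# whose integrated position peaks at a configured date (around the fall
# equinox), a westward homing component switched on when the individual's
# von Bertalanffy-grown size crosses a per-individual threshold, and an
# isotropic foraging random walk. Reported positions carry Argos-like
# noise. Identical config + seed gives identical output.

#' Synthetic world configuration
#'
#' Defaults state the reference conditions: basin 20-55 degN x
#' 120-250 degE on a 0.5 degree grid; zonal current 0.04 m/s at the eastern
#' edge growing to 0.11 m/s at the western edge within the 30-45 degN band;
#' clockwise Stokes gyre of magnitude 0.05 m/s; leeway fractions 0.88
#' (drifters) and 0.28 (turtles); seasonal meridional migration of 440 km
#' positional amplitude peaking on day-of-year 264 (Sept 21); westward
#' homing at 0.09-0.15 m/s growing linearly with size between 35 and 55 cm
#' SCL; homing trigger sizes Normal(42, 4) cm; foraging random walk std
#' 0.05 m/s; drifter process-noise std 0.05 m/s; Argos position noise std
#' 1000 m per component.
#'
#' @param seed integer seed; the whole generated world is a deterministic
#'   function of the config including this seed.
#' @param n_drifters,n_turtles population sizes.
#' @param n_days tracking duration (days).
#' @param start_date first tracked day.
#' @param grid_step field grid spacing (degrees).
#' @param gamma_drifter,gamma_turtle planted leeway fractions.
#' @param current_east,current_west zonal current at the eastern/western
#'   edges of the 30-45 degN band (m/s).
#' @param stokes_magnitude Stokes gyre magnitude (m/s).
#' @param stokes_synoptic_std std (m/s per component) of an optional
#'   basin-wide daily Stokes anomaly emulating wave-weather variability
#'   (default 0: the reference world is the steady gyre). Because the
#'   midnight-interpolated velocity over ground is a two-day smoother,
#'   fast anomalies attenuate the fitted leeway fraction; this knob exists
#'   for sensitivity experiments, not for the reference world.
#' @param stokes_synoptic_ar1 lag-1 autocorrelation of the synoptic anomaly
#'   (default 0.7, a few-day storm decorrelation time).
#' @param seasonal_amplitude_km positional amplitude of the seasonal
#'   meridional migration (km); the swim velocity amplitude is
#'   \code{amplitude * omega}.
#' @param peak_doy day-of-year at which the meridional position peaks.
#' @param homing_speed_range westward homing speed (m/s) at 35 cm and at
#'   55+ cm SCL; linear in between.
#' @param trigger_scl_mean,trigger_scl_sd per-individual homing trigger
#'   size distribution (cm, truncated positive).
#' @param foraging_rw_std isotropic swim random-walk std (m/s).
#' @param process_noise_std drifter drift process noise std (m/s).
#' @param argos_noise_std reported-position noise std (m per component).
#' @param release_lat,release_lon release area (degrees).
#' @param release_scl_range turtle release size range (cm, uniform).
#' @param release_spread_days individuals are released at dates drawn
#'   uniformly within this many days of \code{start_date} (default 365,
#'   emulating a multi-year tracking program; 0 releases everyone together).
#' @return list of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1L,
                         n_drifters = 200L, n_turtles = 100L, n_days = 300L,
                         start_date = as.Date("2005-01-01"),
                         grid_step = 0.5,
                         gamma_drifter = 0.88, gamma_turtle = 0.28,
                         current_east = 0.04, current_west = 0.11,
                         stokes_magnitude = 0.05,
                         stokes_synoptic_std = 0,
                         stokes_synoptic_ar1 = 0.7,
                         seasonal_amplitude_km = 440, peak_doy = 264,
                         homing_speed_range = c(0.09, 0.15),
                         trigger_scl_mean = 42, trigger_scl_sd = 4,
                         foraging_rw_std = 0.05,
                         process_noise_std = 0.05,
                         argos_noise_std = 1000,
                         release_lat = c(28, 42), release_lon = c(150, 220),
                         release_scl_range = c(30, 45),
                         release_spread_days = 365L) {
  structure(list(
    seed = as.integer(seed),
    domain_lat = c(20, 55), domain_lon = c(120, 250),
    n_drifters = n_drifters, n_turtles = n_turtles, n_days = n_days,
    start_date = as.Date(start_date), grid_step = grid_step,
    gamma_drifter = gamma_drifter, gamma_turtle = gamma_turtle,
    current_east = current_east, current_west = current_west,
    stokes_magnitude = stokes_magnitude,
    stokes_synoptic_std = stokes_synoptic_std,
    stokes_synoptic_ar1 = stokes_synoptic_ar1,
    seasonal_amplitude_km = seasonal_amplitude_km, peak_doy = peak_doy,
    homing_speed_range = homing_speed_range,
    trigger_scl_mean = trigger_scl_mean, trigger_scl_sd = trigger_scl_sd,
    foraging_rw_std = foraging_rw_std,
    process_noise_std = process_noise_std,
    argos_noise_std = argos_noise_std,
    release_lat = release_lat, release_lon = release_lon,
    release_scl_range = release_scl_range,
    release_spread_days = as.integer(release_spread_days)
  ), class = "synth_config")
}

# analytic field formulas, vectorized over (lat, lon) of equal length
.synth_current_u <- function(cfg, lat, lon) {
  # plateau in 30-45N with 10-degree cosine ramps; the ramps are kept gentle
  # so the daily discretization error of the estimator (half the along-track
  # field change per day) stays well below 1e-3 m/s
  band <- rep(0, length(lat))
  core <- lat >= 30 & lat <= 45
  band[core] <- 1
  lo <- lat > 20 & lat < 30
  band[lo] <- 0.5 * (1 - cos(pi * (lat[lo] - 20) / 10))
  hi <- lat > 45 & lat < 55
  band[hi] <- 0.5 * (1 + cos(pi * (lat[hi] - 45) / 10))
  frac_west <- (cfg$domain_lon[2] - lon) / diff(cfg$domain_lon)
  band * (cfg$current_east + (cfg$current_west - cfg$current_east) * frac_west)
}

.synth_current_v <- function(cfg, lat, lon) rep(0, length(lat))

.synth_stokes_u <- function(cfg, lat, lon) {
  cfg$stokes_magnitude * (lat - mean(cfg$domain_lat)) / (diff(cfg$domain_lat) / 2)
}

.synth_stokes_v <- function(cfg, lat, lon) {
  -cfg$stokes_magnitude * (lon - mean(cfg$domain_lon)) / (diff(cfg$domain_lon) / 2)
}

#' Generate the synthetic gridded field set
#'
#' Evaluates the analytic current and Stokes formulas at the grid nodes.
#' The gridded part is time-invariant (a static \code{field_set}); the
#' synoptic part of the Stokes drift is a basin-wide daily AR(1) anomaly
#' covering the full simulation span, seeded from the config so that the
#' advection and the later field matching see exactly the same product.
#'
#' @param config a \code{\link{synth_config}}.
#' @return a \code{field_set}.
#' @export
gen_fields <- function(config) {
  lat <- seq(config$domain_lat[1], config$domain_lat[2], by = config$grid_step)
  lon <- seq(config$domain_lon[1], config$domain_lon[2], by = config$grid_step)
  g <- expand.grid(lat = lat, lon = lon, KEEP.OUT.ATTRS = FALSE)
  shape <- function(x) matrix(x, nrow = length(lat))
  anom <- NULL
  if (config$stokes_synoptic_std > 0) {
    ndays <- config$n_days + config$release_spread_days
    set.seed(config$seed + 2000003L)
    phi <- config$stokes_synoptic_ar1
    innov_sd <- config$stokes_synoptic_std * sqrt(1 - phi^2)
    ar1 <- function() as.numeric(stats::arima.sim(
      list(ar = phi), ndays, sd = innov_sd))
    anom <- data.frame(date = config$start_date + 0:(ndays - 1L),
                       du = ar1(), dv = ar1())
  }
  field_set(lat, lon,
            u_co = shape(.synth_current_u(config, g$lat, g$lon)),
            v_co = shape(.synth_current_v(config, g$lat, g$lon)),
            u_sto = shape(.synth_stokes_u(config, g$lat, g$lon)),
            v_sto = shape(.synth_stokes_v(config, g$lat, g$lon)),
            stokes_anom = anom)
}

# daily Euler advection shared by drifters and turtles.
# swim_fun(elapsed_day_per_individual, lat, lon, active) returns a
# list(u, v) of swimming velocities (zero for drifters). Individuals are
# released at staggered dates (uniform over release_spread_days) as in the
# multi-year tracking programs the generator emulates; this also keeps the
# programmed swimming decorrelated from the purely spatial Stokes gyre.
# Returns observed tracks + truth table.
.advect <- function(config, fields, n, gamma, swim_fun, prefix, group,
                    process_noise_std) {
  n_days <- config$n_days
  spread <- config$release_spread_days
  start_off <- if (spread > 0) sample.int(spread, n, replace = TRUE) - 1L else
    integer(n)
  lat <- stats::runif(n, config$release_lat[1], config$release_lat[2])
  lon <- stats::runif(n, config$release_lon[1], config$release_lon[2])
  alive <- rep(TRUE, n)     # FALSE once the individual exits the basin
  total <- n_days + max(start_off)
  dates <- config$start_date + 0:(total - 1L)
  obs <- truth <- vector("list", total)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  for (d in seq_len(total)) {
    elapsed <- d - start_off          # individual day count, 1 = release day
    a <- which(alive & elapsed >= 1L & elapsed <= n_days)
    if (!length(a)) next
    cur <- sample_bilinear(fields, dates[d], lat[a], lon[a], "current")
    sto <- sample_bilinear(fields, dates[d], lat[a], lon[a], "stokes")
    sw <- swim_fun(dates[d], elapsed[a], lat[a], lon[a], a)
    eta_u <- stats::rnorm(length(a), 0, process_noise_std)
    eta_v <- stats::rnorm(length(a), 0, process_noise_std)
    vd_u <- cur$u + gamma * sto$u + eta_u
    vd_v <- cur$v + gamma * sto$v + eta_v
    u <- vd_u + sw$u
    v <- vd_v + sw$v
    # observed position: true + Argos noise, in meters converted locally
    err_lat <- stats::rnorm(length(a), 0, config$argos_noise_std) / m_per_deg_lat()
    err_lon <- stats::rnorm(length(a), 0, config$argos_noise_std) / m_per_deg_lon(lat[a])
    obs[[d]] <- data.frame(id = ids[a], date = dates[d],
                           lat = lat[a] + err_lat, lon = lon[a] + err_lon,
                           stringsAsFactors = FALSE)
    truth[[d]] <- data.frame(id = ids[a], date = dates[d],
                             lat_true = lat[a], lon_true = lon[a],
                             vd_u = vd_u, vd_v = vd_v,
                             vs_u = sw$u, vs_v = sw$v,
                             stringsAsFactors = FALSE)
    # Euler step
    lat[a] <- lat[a] + v * 86400 / m_per_deg_lat()
    lon[a] <- lon[a] + u * 86400 / m_per_deg_lon(lat[a])
    out <- lat[a] < config$domain_lat[1] | lat[a] > config$domain_lat[2] |
           lon[a] < config$domain_lon[1] | lon[a] > config$domain_lon[2]
    alive[a[out]] <- FALSE
  }
  tracks <- do.call(rbind, obs)
  truth <- do.call(rbind, truth)
  tracks <- tracks[order(tracks$id, tracks$date), , drop = FALSE]
  truth <- truth[order(truth$id, truth$date), , drop = FALSE]
  tracks$group <- group
  truth$gamma_true <- gamma
  rownames(tracks) <- rownames(truth) <- NULL
  list(tracks = tracks, truth = truth,
       release_date = config$start_date + start_off)
}

#' Generate passive synthetic drifters
#'
#' Daily Euler advection \code{X(t+1) = X(t) + (V_co + gamma V_sto + eta) dt}
#' with isotropic Gaussian process noise eta, truncated when a drifter exits
#' the basin. Reported positions carry Argos-like noise; the truth table
#' keeps noise-free positions, true drift velocities and the planted gamma.
#'
#' @param config a \code{\link{synth_config}}.
#' @param fields a \code{field_set} covering the domain (defaults to
#'   \code{gen_fields(config)}).
#' @return list: tracks (observed track table), truth (truth table).
#' @export
gen_drifters <- function(config, fields = gen_fields(config)) {
  set.seed(config$seed)
  zero_swim <- function(date, el, lat, lon, a) list(u = rep(0, length(lat)),
                                                   v = rep(0, length(lat)))
  .advect(config, fields, config$n_drifters, config$gamma_drifter, zero_swim,
          "drf", "drifter", config$process_noise_std)
}

# westward homing speed as a function of size (m/s, positive magnitude)
.homing_speed <- function(config, scl) {
  lo <- config$homing_speed_range[1]; hi <- config$homing_speed_range[2]
  frac <- pmin(pmax((scl - 35) / 20, 0), 1)
  lo + (hi - lo) * frac
}

#' Generate behaviorally programmed synthetic turtles
#'
#' Like \code{\link{gen_drifters}} with the turtle leeway fraction, plus a
#' programmed swimming velocity: a meridional sinusoid whose integrated
#' position peaks on the configured day-of-year (the velocity leads the
#' position by a quarter period), a westward component of
#' size-dependent magnitude switched on permanently once the individual's
#' imputed size crosses its trigger threshold, and an isotropic foraging
#' random walk. Sizes grow along the von Bertalanffy curve from a
#' per-individual release size; triggers are drawn
#' Normal(trigger_scl_mean, trigger_scl_sd) truncated positive.
#'
#' @param config a \code{\link{synth_config}}.
#' @param fields a \code{field_set} (defaults to \code{gen_fields(config)}).
#' @param growth \code{\link{growth_params}} used to grow sizes.
#' @return list: tracks (with \code{release_scl}), truth (adds per-day
#'   swimming velocity), individuals (id, release_scl, trigger_scl,
#'   trigger_date -- NA if never fired).
#' @export
gen_turtles <- function(config, fields = gen_fields(config),
                        growth = growth_params()) {
  set.seed(config$seed + 1000003L)
  n <- config$n_turtles
  l0 <- stats::runif(n, config$release_scl_range[1], config$release_scl_range[2])
  trig <- stats::rnorm(n, config$trigger_scl_mean, config$trigger_scl_sd)
  while (any(trig <= 0)) trig[trig <= 0] <- stats::rnorm(sum(trig <= 0),
                              config$trigger_scl_mean, config$trigger_scl_sd)
  # daily sizes: n x n_days matrix over elapsed days, vB growth in
  # 365.25-day years
  dt_yr <- (0:(config$n_days - 1L)) / 365.25
  scl <- growth$l_inf - outer(growth$l_inf - l0, exp(-growth$k * dt_yr))
  homing_on <- scl >= matrix(trig, n, config$n_days)
  amp_m <- config$seasonal_amplitude_km * 1000
  omega_day <- 2 * pi / 365.25
  # y(t) = A cos(omega (doy - peak)) peaks at peak_doy; v = dy/dt
  v_season_at <- function(date) {
    -amp_m * omega_day * sin(omega_day * (.doy(date) - config$peak_doy)) / 86400
  }
  swim <- function(date, el, lat, lon, a) {
    ix <- cbind(a, el)
    u_home <- ifelse(homing_on[ix], -.homing_speed(config, scl[ix]), 0)
    k <- length(a)
    list(u = u_home + stats::rnorm(k, 0, config$foraging_rw_std),
         v = v_season_at(date) + stats::rnorm(k, 0, config$foraging_rw_std))
  }
  res <- .advect(config, fields, n, config$gamma_turtle, swim,
                 "ttl", "synthetic", 0)
  ids <- sprintf("ttl%03d", seq_len(n))
  res$tracks$release_scl <- l0[match(res$tracks$id, ids)]
  trig_day <- apply(homing_on, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  res$individuals <- data.frame(
    id = ids, release_scl = l0, trigger_scl = trig,
    trigger_date = res$release_date + (trig_day - 1L),
    stringsAsFactors = FALSE)
  res
}
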
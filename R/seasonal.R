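# Seasonal (meridional) migration analysis: annual sine fitting of the
# meridional DC-trajectory, circular phase statistics, latitude x week
# velocity binning, and pooled annual mean meridional DC-trajectories.

.OMEGA <- 2 * pi / 365.25   # annual angular frequency, per day

#' Fit an annual sine to a meridional DC-trajectory
#'
#' Least-squares fit of
#' \deqn{y_{DC}(t) = c + b t + A \sin(\omega t + \theta)}
#' with the period fixed at 365.25 days, linear in
#' (c, b, A cos\theta, A sin\theta) so the normal equations solve it
#' directly. The linear trend absorbs non-seasonal meridional drift and can
#' be switched off for sensitivity checks. The reported phase is the
#' day-of-year at which the sine component (not the trend-shifted curve)
#' reaches its maximum. Tracks spanning more than a full year give the most
#' reliable amplitude/phase estimates and are flagged \code{eligible}.
#'
#' @param dates Date vector of daily records.
#' @param y_dc meridional DC-trajectory (km).
#' @param trend include a linear trend term (default TRUE).
#' @return object of class \code{annual_sine}: amplitude (km, >= 0),
#'   peak_doy (day-of-year of the sine maximum, in [1, 366)), offset, trend
#'   (km/day), rms_residual (km), eligible (span > 365 days), n, unreliable
#'   (TRUE when the design is degenerate).
#' @export
fit_annual_sine <- function(dates, y_dc, trend = TRUE) {
  ok <- !is.na(y_dc)
  dates <- dates[ok]; y <- y_dc[ok]
  n <- length(y)
  if (n < 30) stop("need at least 30 daily values to fit an annual sine")
  t <- as.numeric(dates)                     # days since 1970-01-01
  # trend column centered for conditioning; sine columns keep absolute phase
  X <- cbind(1, if (trend) t - mean(t) else NULL, sin(.OMEGA * t), cos(.OMEGA * t))
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  unreliable <- any(is.na(co)) || kappa(crossprod(X)) > 1e12
  co[is.na(co)] <- 0
  k <- length(co)
  a_s <- unname(co[k - 1]); a_c <- unname(co[k])   # y ~ a_s sin(wt) + a_c cos(wt)
  amplitude <- sqrt(a_s^2 + a_c^2)
  theta <- atan2(a_c, a_s)                   # y = A sin(wt + theta)
  # sine max where w t + theta = pi/2 (mod 2pi)
  t_peak <- (pi / 2 - theta) / .OMEGA
  t_peak <- t_peak + 365.25 * ceiling((t[1] - t_peak) / 365.25)
  peak_doy <- .doy(as.Date(round(t_peak), origin = "1970-01-01"))
  res <- y - X %*% co
  structure(list(
    amplitude = amplitude, peak_doy = peak_doy,
    offset = unname(co[1]),
    trend = if (trend) unname(co[2]) else 0,
    rms_residual = sqrt(mean(res^2)),
    eligible = as.integer(max(dates) - min(dates)) > 365,
    n = n, unreliable = unreliable
  ), class = "annual_sine")
}

#' @export
print.annual_sine <- function(x, ...) {
  cat(sprintf("annual sine: amplitude %.1f km, peak day-of-year %d, trend %.3f km/d, rms %.1f km%s\n",
              x$amplitude, x$peak_doy, x$trend, x$rms_residual,
              if (x$eligible) "" else " (track <= 1 yr)"))
  invisible(x)
}

#' @export
coef.annual_sine <- function(object, ...) {
  c(amplitude_km = object$amplitude, peak_doy = object$peak_doy,
    offset_km = object$offset, trend_km_per_day = object$trend)
}

#' Fit annual sines to every track
#' @param tracks track data.frame with y_dc_km.
#' @param trend include a linear trend (default TRUE).
#' @return data.frame: id, amplitude_km, peak_doy, trend, rms, eligible.
#' @export
fit_annual_sines <- function(tracks, trend = TRUE) {
  rows <- lapply(split(tracks, tracks$id), function(d) {
    if (sum(!is.na(d$y_dc_km)) < 30) return(NULL)
    f <- fit_annual_sine(d$date, d$y_dc_km, trend = trend)
    data.frame(id = d$id[1], amplitude_km = f$amplitude, peak_doy = f$peak_doy,
               trend = f$trend, rms = f$rms_residual, eligible = f$eligible,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Circular mean of seasonal phases
#'
#' Maps day-of-year phases onto the unit circle (angle
#' \code{2 pi doy / 365.25}), averages the unit vectors, and converts the
#' resultant angle back to a day-of-year. Antipodal/uniform phase sets with
#' resultant length below 1e-6 have no defined mean and raise an error.
#'
#' @param peak_doy numeric vector of day-of-year phases.
#' @return list: mean_doy, resultant_length (in [0, 1]), n.
#' @export
circular_mean_phase <- function(peak_doy) {
  peak_doy <- peak_doy[!is.na(peak_doy)]
  if (length(peak_doy) < 1) stop("no phases given")
  ang <- 2 * pi * peak_doy / 365.25
  C <- mean(cos(ang)); S <- mean(sin(ang))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-6) stop("resultant length ~ 0: circular mean undefined")
  mu <- atan2(S, C) %% (2 * pi)
  list(mean_doy = mu * 365.25 / (2 * pi), resultant_length = R, n = length(peak_doy))
}

#' Mean meridional DC-velocity in latitude x week boxes
#'
#' Pools all daily meridional DC-velocities into [1 degree latitude x 7 day]
#' boxes of (latitude, week-of-year) and reports the mean and count per box.
#' Boxes supported by \code{min_count} samples or fewer are masked.
#'
#' @param tracks track data.frame with lat, v_dc and date columns.
#' @param min_count mask boxes with count <= min_count (default 50, i.e.
#'   only boxes with more than 50 samples are shown).
#' @return data.frame: lat0 (box lower edge), week (1..53), mean_v_dc
#'   (NA when masked), n.
#' @export
binned_meridional_means <- function(tracks, min_count = 50) {
  ok <- !is.na(tracks$v_dc)
  d <- tracks[ok, , drop = FALSE]
  lat0 <- floor(d$lat)
  week <- pmin((.doy(d$date) - 1L) %/% 7L + 1L, 53L)
  key <- paste(lat0, week, sep = "_")
  rows <- lapply(split(seq_len(nrow(d)), key), function(ix) {
    data.frame(lat0 = lat0[ix[1]], week = week[ix[1]],
               mean_v_dc = mean(d$v_dc[ix]), n = length(ix))
  })
  out <- do.call(rbind, rows)
  out$mean_v_dc[out$n <= min_count] <- NA_real_
  out <- out[order(out$lat0, out$week), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annual mean meridional DC-trajectory of a behavioral subset
#'
#' Sorts all daily meridional DC-velocities of the subset by day-of-year,
#' computes the mean velocity for each of the 365 days (pooling every
#' segment-day equally), linearly gap-fills empty days (periodically, with a
#' message), and integrates from January 1 to December 31. The migration
#' distance is the range (max - min) of the integrated trajectory.
#'
#' @param tracks track data.frame with v_dc and date columns, already
#'   restricted to the desired behavioral subset (e.g. the days of valid D
#'   or H segments).
#' @return list: doy (1..365), mean_v_dc (m/s), y_km (cumulative integral,
#'   km), migration_distance_km, n_filled (gap-filled days).
#' @export
annual_mean_meridional_trajectory <- function(tracks) {
  ok <- !is.na(tracks$v_dc)
  d <- tracks[ok, , drop = FALSE]
  doy <- pmin(.doy(d$date), 365L)            # fold Dec 31 of leap years
  mv <- rep(NA_real_, 365)
  agg <- tapply(d$v_dc, doy, mean)
  mv[as.integer(names(agg))] <- agg
  n_filled <- sum(is.na(mv))
  if (n_filled > 0) {
    if (n_filled >= 364) stop("not enough data to build an annual trajectory")
    message(n_filled, " empty day(s)-of-year linearly gap-filled")
    # periodic linear interpolation: replicate the year on both sides
    idx <- which(!is.na(mv))
    mv <- stats::approx(x = c(idx - 365, idx, idx + 365),
                        y = rep(mv[idx], 3), xout = 1:365)$y
  }
  y <- cumsum(mv) * 86400 / 1000
  list(doy = 1:365, mean_v_dc = mv, y_km = y,
       migration_distance_km = max(y) - min(y), n_filled = n_filled)
}

#' Seasonal mean DC-velocity vectors
#'
#' Mean (u_dc, v_dc) over the meteorological seasons DJF, MAM, JJA, SON of
#' the pooled subset days.
#'
#' @param tracks track data.frame with u_dc, v_dc, date.
#' @return data.frame: season, mean_u_dc, mean_v_dc, n (seasons with no data
#'   are absent).
#' @export
seasonal_vectors <- function(tracks) {
  ok <- !is.na(tracks$u_dc) & !is.na(tracks$v_dc)
  d <- tracks[ok, , drop = FALSE]
  mo <- as.integer(format(d$date, "%m"))
  season <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
              "JJA", "JJA", "SON", "SON", "SON", "DJF")[mo]
  rows <- lapply(split(seq_len(nrow(d)), season), function(ix) {
    data.frame(season = season[ix[1]],
               mean_u_dc = mean(d$u_dc[ix]), mean_v_dc = mean(d$v_dc[ix]),
               n = length(ix), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[match(c("DJF", "MAM", "JJA", "SON"), out$season), , drop = FALSE]
  out <- out[!is.na(out$season), , drop = FALSE]
  rownames(out) <- NULL
  out
}
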
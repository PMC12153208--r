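# Drift-corrected (DC) velocities and trajectories.
#
# The DC-velocity is the velocity over ground minus the modeled drift
# velocity; for a swimming animal it estimates the swimming velocity, for a
# passive drifter it is a direct measure of the estimation noise. Its time
# integral (the DC-trajectory) lives in a local (x, y) plane with origin
# (0, 0) at the start of the track, not on the Earth surface.

#' Compute daily DC-velocities
#'
#' \code{V_DC = V_g - (V_co + gamma * V_sto)} per day. Days missing any
#' input stay missing.
#'
#' @param tracks track data.frame with vg_* and matched vco_*, vsto_*.
#' @param model a \code{leeway_fit} or bare numeric gamma.
#' @return the track table with \code{u_dc}, \code{v_dc} columns (m/s).
#' @export
dc_velocity <- function(tracks, model) {
  vd <- drift_velocity(tracks, model)
  tracks$u_dc <- tracks$vg_u - vd$u
  tracks$v_dc <- tracks$vg_v - vd$v
  tracks
}

#' Integrate DC-velocities into DC-trajectories
#'
#' Cumulative plane integration of the daily DC-velocity: the value stored
#' on day k is the position (km) at the end of day k, the origin (0, 0)
#' being the start of the track's first day. Days with missing DC-velocity
#' contribute zero displacement; their count is recorded in the
#' \code{"n_gap_days"} attribute rather than silently interpolated.
#'
#' @param tracks track data.frame with u_dc, v_dc columns.
#' @return the track table with \code{x_dc_km}, \code{y_dc_km} columns.
#' @export
dc_trajectory <- function(tracks) {
  stopifnot(all(c("u_dc", "v_dc") %in% names(tracks)))
  tracks <- tracks[order(match(tracks$id, unique(tracks$id)), tracks$date), , drop = FALSE]
  tracks$x_dc_km <- NA_real_
  tracks$y_dc_km <- NA_real_
  n_gap <- 0L
  for (ix in split(seq_len(nrow(tracks)), tracks$id)) {
    u <- tracks$u_dc[ix]; v <- tracks$v_dc[ix]
    n_gap <- n_gap + sum(is.na(u) | is.na(v))
    u[is.na(u)] <- 0; v[is.na(v)] <- 0
    tracks$x_dc_km[ix] <- cumsum(u) * 86400 / 1000
    tracks$y_dc_km[ix] <- cumsum(v) * 86400 / 1000
  }
  attr(tracks, "n_gap_days") <- n_gap
  tracks
}

#' Ensemble statistics of DC-trajectories
#'
#' Per elapsed day, the mean and per-component standard deviation of
#' \code{x_dc} and \code{y_dc} over all tracks still tracked on that day.
#' Rows where fewer than \code{min_n} tracks remain are masked (NA), as in
#' the ensemble figures where curves are discontinued below 20 trajectories.
#' In \code{"calendar_jan1"} mode each track's clock starts on January 1 of
#' its release year (elapsed day 1 = Jan 1), aligning seasonal signals
#' across individuals; positions still start at the track origin.
#'
#' @param tracks track data.frame with x_dc_km, y_dc_km columns.
#' @param origin_mode \code{"release"} (elapsed days since first record) or
#'   \code{"calendar_jan1"}.
#' @param min_n minimum ensemble size before masking (default 20).
#' @return data.frame: elapsed_day, n, mean_x, std_x, mean_y, std_y.
#' @export
ensemble_stats <- function(tracks, origin_mode = c("release", "calendar_jan1"),
                           min_n = 20) {
  origin_mode <- match.arg(origin_mode)
  stopifnot(all(c("x_dc_km", "y_dc_km") %in% names(tracks)))
  pieces <- lapply(split(tracks, tracks$id), function(d) {
    d <- d[order(d$date), , drop = FALSE]
    t0 <- if (origin_mode == "release") d$date[1] else
      as.Date(paste0(format(d$date[1], "%Y"), "-01-01"))
    data.frame(elapsed_day = as.integer(d$date - t0) + 1L,
               x = d$x_dc_km, y = d$y_dc_km)
  })
  all <- do.call(rbind, pieces)
  all <- all[!is.na(all$x) & !is.na(all$y), , drop = FALSE]
  days <- sort(unique(all$elapsed_day))
  out <- data.frame(elapsed_day = days, n = NA_integer_,
                    mean_x = NA_real_, std_x = NA_real_,
                    mean_y = NA_real_, std_y = NA_real_)
  grp <- split(seq_len(nrow(all)), all$elapsed_day)
  for (k in seq_along(days)) {
    ix <- grp[[as.character(days[k])]]
    out$n[k] <- length(ix)
    if (length(ix) >= min_n) {
      out$mean_x[k] <- mean(all$x[ix]); out$std_x[k] <- stats::sd(all$x[ix])
      out$mean_y[k] <- mean(all$y[ix]); out$std_y[k] <- stats::sd(all$y[ix])
    }
  }
  out
}

#' Drifter DC-velocity samples for noise maps
#'
#' Computes drifter DC-velocities under a stated drift-model variant and
#' returns position-tagged samples ready for \code{\link{box_statistics}}.
#' Contrasting \code{gamma = 0} (current-only drift) with the fitted gamma
#' reproduces the with/without-leeway comparison used to map the estimation
#' noise of the method.
#'
#' @param tracks drifter track data.frame with vg_* and matched fields.
#' @param model a \code{leeway_fit} or bare gamma; use 0 for the
#'   current-only variant.
#' @return data.frame lat, lon, u, v suitable for \code{box_statistics}.
#' @export
noise_maps <- function(tracks, model) {
  d <- dc_velocity(tracks, model)
  data.frame(lat = d$lat, lon = d$lon, u = d$u_dc, v = d$v_dc)
}

#' Write per-elapsed-day ensemble statistics to CSV
#' @param stats output of \code{\link{ensemble_stats}}.
#' @param path output path.
#' @export
write_ensemble_stats <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
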
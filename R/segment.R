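# Two-segment breakpoint detection on zonal DC-velocities and the
# drifting / homing / unreliable taxonomy.
#
# Every trajectory is systematically split into exactly two segments at the
# breakpoint minimizing the total sum of squared deviations of the daily
# zonal DC-velocity about the two per-segment means (a two-regime constant
# mean model, equivalently a continuous two-piece linear fit to the zonal
# DC-trajectory). Segments are then classified: homing (H) when the mean
# zonal DC-velocity is below -6.5 cm/s, drifting (D) otherwise, unreliable
# (U) when shorter than 90 days or noisier than 0.25 m/s std -- the U checks
# take precedence.

#' Default classification thresholds
#'
#' homing_threshold: mean zonal DC-velocity (m/s) below which a segment is
#' homing; min_segment_days: minimum calendar duration of a reliable
#' segment; max_segment_std: maximum std of daily zonal DC-velocity of a
#' reliable segment.
#' @export
segment_thresholds <- function(homing_threshold = -0.065,
                               min_segment_days = 90,
                               max_segment_std = 0.25) {
  list(homing_threshold = homing_threshold,
       min_segment_days = min_segment_days,
       max_segment_std = max_segment_std)
}

#' Detect the two-segment breakpoint of a zonal DC-velocity series
#'
#' Returns the index b (length of the first segment, 1 <= b <= n-1)
#' minimizing the pooled sum of squared deviations about the two segment
#' means. Missing days are excluded from the sums but keep their calendar
#' position. Ties are broken by the earliest b. Runs in O(n) via prefix
#' sums.
#'
#' @param u numeric vector of daily zonal DC-velocities (NA allowed).
#' @return integer breakpoint index, or NA if the series has fewer than 2
#'   days.
#' @export
detect_breakpoint <- function(u) {
  n <- length(u)
  if (n < 2) return(NA_integer_)
  ok <- !is.na(u)
  x <- ifelse(ok, u, 0)
  cs <- cumsum(x); cs2 <- cumsum(x^2); cn <- cumsum(ok)
  tot_s <- cs[n]; tot_s2 <- cs2[n]; tot_n <- cn[n]
  b <- seq_len(n - 1L)
  n1 <- cn[b]; s1 <- cs[b]
  n2 <- tot_n - n1; s2 <- tot_s - s1
  sse <- tot_s2 - ifelse(n1 > 0, s1^2 / n1, 0) - ifelse(n2 > 0, s2^2 / n2, 0)
  which.min(sse)  # which.min returns the first (earliest) minimum
}

#' Classify one segment as drifting, homing or unreliable
#'
#' Unreliability (too short or too noisy) takes precedence over the sign
#' rule: a 60-day segment with a strongly negative mean is U, not H.
#'
#' @param duration_days calendar duration of the segment.
#' @param mean_u_dc mean daily zonal DC-velocity (m/s) over non-missing days.
#' @param std_u_dc std of the daily zonal DC-velocity (m/s).
#' @param thresholds see \code{\link{segment_thresholds}}.
#' @return one of "D", "H", "U".
#' @export
classify_segment <- function(duration_days, mean_u_dc, std_u_dc,
                             thresholds = segment_thresholds()) {
  if (is.na(duration_days) || duration_days < thresholds$min_segment_days) return("U")
  if (is.na(std_u_dc) || std_u_dc > thresholds$max_segment_std) return("U")
  if (is.na(mean_u_dc)) return("U")
  if (mean_u_dc < thresholds$homing_threshold) "H" else "D"
}

.segment_stats <- function(dates, u) {
  ok <- !is.na(u)
  data.frame(
    start_date = dates[1], end_date = dates[length(dates)],
    duration = as.integer(dates[length(dates)] - dates[1]) + 1L,
    mean_u_dc = if (any(ok)) mean(u[ok]) else NA_real_,
    std_u_dc = if (sum(ok) > 1) stats::sd(u[ok]) else NA_real_
  )
}

#' Classify a single trajectory (two-segment taxonomy)
#'
#' Applies \code{\link{detect_breakpoint}} to the zonal DC-velocity, then
#' classifies both segments and maps the pair onto the trajectory taxonomy:
#' U (shorter than the minimum duration, or two U segments), D_only (DD or
#' D with one U), H_only (HH or H with one U), DH (drifting then homing) or
#' HD (homing then drifting). For DH trajectories the breakpoint date (first
#' day of the homing segment) and, when a daily \code{scl} column is
#' present, the size at the breakpoint are recorded.
#'
#' @param track data.frame for one individual with columns date, u_dc and
#'   optionally scl.
#' @param thresholds see \code{\link{segment_thresholds}}.
#' @return a list of class \code{trajectory_class}: id, klass,
#'   breakpoint_date, breakpoint_scl, segments (two-row data.frame).
#' @export
classify_trajectory <- function(track, thresholds = segment_thresholds()) {
  track <- track[order(track$date), , drop = FALSE]
  id <- if ("id" %in% names(track)) as.character(track$id[1]) else NA_character_
  n <- nrow(track)
  total_days <- if (n > 0) as.integer(track$date[n] - track$date[1]) + 1L else 0L
  empty <- structure(list(id = id, klass = "U", breakpoint_date = as.Date(NA),
                          breakpoint_scl = NA_real_, segments = NULL),
                     class = "trajectory_class")
  if (n < 2 || total_days < thresholds$min_segment_days) return(empty)
  b <- detect_breakpoint(track$u_dc)
  i1 <- seq_len(b); i2 <- seq.int(b + 1L, n)
  seg <- rbind(.segment_stats(track$date[i1], track$u_dc[i1]),
               .segment_stats(track$date[i2], track$u_dc[i2]))
  seg$klass <- c(
    classify_segment(seg$duration[1], seg$mean_u_dc[1], seg$std_u_dc[1], thresholds),
    classify_segment(seg$duration[2], seg$mean_u_dc[2], seg$std_u_dc[2], thresholds))
  k1 <- seg$klass[1]; k2 <- seg$klass[2]
  klass <- if (k1 == "U" && k2 == "U") "U"
  else if (k1 == "D" && k2 == "H") "DH"
  else if (k1 == "H" && k2 == "D") "HD"
  else if ("H" %in% c(k1, k2)) "H_only"
  else "D_only"
  bp_date <- as.Date(NA); bp_scl <- NA_real_
  if (klass %in% c("DH", "HD")) {
    bp_date <- track$date[b + 1L]
    if ("scl" %in% names(track)) bp_scl <- track$scl[b + 1L]
  }
  structure(list(id = id, klass = klass, breakpoint_date = bp_date,
                 breakpoint_scl = bp_scl, segments = seg),
            class = "trajectory_class")
}

#' @export
print.trajectory_class <- function(x, ...) {
  cat("trajectory", x$id, "->", x$klass)
  if (!is.na(x$breakpoint_date)) cat("  breakpoint", format(x$breakpoint_date))
  if (!is.na(x$breakpoint_scl)) cat(sprintf("  (SCL %.1f cm)", x$breakpoint_scl))
  cat("\n")
  if (!is.null(x$segments)) print(x$segments)
  invisible(x)
}

#' Classify every trajectory in a track table
#'
#' @param tracks track data.frame with u_dc (and optionally scl) columns.
#' @param thresholds see \code{\link{segment_thresholds}}.
#' @return data.frame with one row per id: klass, breakpoint_date,
#'   breakpoint_scl and per-segment start/end/mean/std/class columns.
#' @export
classify_tracks <- function(tracks, thresholds = segment_thresholds()) {
  rows <- lapply(split(tracks, tracks$id), function(d) {
    tc <- classify_trajectory(d, thresholds)
    seg <- tc$segments
    f <- function(k, col) if (is.null(seg)) NA_real_ else seg[[col]][k]
    fd <- function(k, col) if (is.null(seg)) as.Date(NA) else seg[[col]][k]
    fc <- function(k) if (is.null(seg)) NA_character_ else seg$klass[k]
    data.frame(
      id = tc$id, klass = tc$klass,
      breakpoint_date = tc$breakpoint_date, breakpoint_scl = tc$breakpoint_scl,
      seg1_start = fd(1, "start_date"), seg1_end = fd(1, "end_date"),
      seg1_mean_u_dc = f(1, "mean_u_dc"), seg1_std_u_dc = f(1, "std_u_dc"),
      seg1_klass = fc(1),
      seg2_start = fd(2, "start_date"), seg2_end = fd(2, "end_date"),
      seg2_mean_u_dc = f(2, "mean_u_dc"), seg2_std_u_dc = f(2, "std_u_dc"),
      seg2_klass = fc(2),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
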
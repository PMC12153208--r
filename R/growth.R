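# von Bertalanffy size imputation, the size-conditional homing probability
# F_H(SCL), and breakpoint seasonality statistics.

#' von Bertalanffy growth parameters
#'
#' Defaults are conservative literature values for North Pacific loggerhead
#' growth: asymptotic straight carapace length 100.06 cm and growth
#' coefficient 0.066 per year. A year is 365.25 days.
#'
#' @param l_inf asymptotic length (cm).
#' @param k growth coefficient (per year).
#' @return list of class \code{growth_params}.
#' @export
growth_params <- function(l_inf = 100.06, k = 0.066) {
  stopifnot(l_inf > 0, k > 0)
  structure(list(l_inf = l_inf, k = k), class = "growth_params")
}

#' Length at age from release size
#'
#' Closed-form von Bertalanffy curve
#' \deqn{L(t) = L_\infty - (L_\infty - L_0) e^{-K (t - t_0)}}
#' with \code{t - t_0} in years of 365.25 days.
#'
#' @param params \code{\link{growth_params}}.
#' @param l0 size at release (cm), must satisfy 0 < l0 < l_inf.
#' @param t0 release date.
#' @param dates dates at which to evaluate (all >= t0).
#' @return SCL in cm at each date; strictly increasing toward l_inf.
#' @export
scl_at <- function(params, l0, t0, dates) {
  stopifnot(l0 > 0, l0 < params$l_inf)
  dt <- as.numeric(as.Date(dates) - as.Date(t0)) / 365.25
  if (any(dt < 0)) stop("date before release date")
  params$l_inf - (params$l_inf - l0) * exp(-params$k * dt)
}

#' Time to grow between two sizes
#' @param params \code{\link{growth_params}}.
#' @param from,to sizes in cm (0 < from <= to < l_inf).
#' @return years (365.25-day years).
#' @export
years_to_grow <- function(params, from, to) {
  stopifnot(from > 0, to >= from, to < params$l_inf)
  log((params$l_inf - from) / (params$l_inf - to)) / params$k
}

#' Impute daily size along each track
#'
#' Evaluates the growth curve at every daily record from the individual's
#' release size and first tracked date. Tracks without a
#' \code{release_scl} keep \code{scl} missing and are excluded downstream.
#'
#' @param tracks track data.frame with a \code{release_scl} column.
#' @param params \code{\link{growth_params}}.
#' @return the track table with a daily \code{scl} column (cm).
#' @export
impute_track_scl <- function(tracks, params = growth_params()) {
  tracks$scl <- NA_real_
  for (ix in split(seq_len(nrow(tracks)), tracks$id)) {
    l0 <- if ("release_scl" %in% names(tracks)) tracks$release_scl[ix][1] else NA_real_
    if (is.na(l0)) next
    t0 <- min(tracks$date[ix])
    tracks$scl[ix] <- scl_at(params, l0, t0, tracks$date[ix])
  }
  tracks
}

#' Size-conditional homing probability F_H(SCL)
#'
#' Estimates, for every size on a regular SCL grid, the probability that an
#' individual has initiated homing before reaching that size, from the
#' classified trajectories under the single-transition assumption (an
#' individual switches from drifting to homing at most once; the rare
#' homing-then-drifting trajectories are excluded). Counting rules per grid
#' size s:
#' \itemize{
#'   \item an individual only tracked drifting (observed sizes up to S1)
#'     counts as drifting for all s <= S1 and is unknown above;
#'   \item an individual only tracked homing (observed sizes from S0)
#'     counts as homing for all s >= S0 and is unknown below;
#'   \item a drifting-then-homing individual with breakpoint size Sb counts
#'     as drifting for s <= Sb and homing for s >= Sb (both at exactly Sb).
#' }
#' Then \code{F_H(s) = n_H(s) / (n_H(s) + n_D(s))}, undefined (NA) where the
#' denominator is zero.
#'
#' @param records data.frame with columns \code{klass} (one of "D_only",
#'   "H_only", "DH"; other classes are dropped), \code{s0}, \code{s1}
#'   (observed SCL range, cm) and \code{sb} (breakpoint SCL, DH rows only).
#' @param s_min,s_max,step SCL grid (defaults 25 to 85 cm by 1 cm).
#' @return object of class \code{homing_cdf}: data.frame scl, n_h, n_d, f_h.
#' @export
estimate_f_h <- function(records, s_min = 25, s_max = 85, step = 1) {
  keep <- records$klass %in% c("D_only", "H_only", "DH")
  r <- records[keep, , drop = FALSE]
  if (any(r$klass == "DH" & is.na(r$sb)))
    stop("DH records must carry a breakpoint size sb")
  grid <- seq(s_min, s_max, by = step)
  n_d <- n_h <- integer(length(grid))
  for (i in seq_along(grid)) {
    s <- grid[i]
    n_d[i] <- sum(r$klass == "D_only" & s <= r$s1) +
              sum(r$klass == "DH" & s <= r$sb)
    n_h[i] <- sum(r$klass == "H_only" & s >= r$s0) +
              sum(r$klass == "DH" & s >= r$sb)
  }
  f_h <- ifelse(n_h + n_d > 0, n_h / (n_h + n_d), NA_real_)
  structure(data.frame(scl = grid, n_h = n_h, n_d = n_d, f_h = f_h),
            class = c("homing_cdf", "data.frame"))
}

#' @export
print.homing_cdf <- function(x, ...) {
  def <- !is.na(x$f_h)
  cat("F_H(SCL) on", min(x$scl), "..", max(x$scl), "cm;",
      sum(def), "of", nrow(x), "grid sizes defined\n")
  for (p in c(0.5, 0.8)) {
    s <- x$scl[def][which(x$f_h[def] >= p)[1]]
    if (!is.na(s)) cat(sprintf("  first SCL with F_H >= %.0f%%: %g cm\n", 100 * p, s))
  }
  invisible(x)
}

#' @export
plot.homing_cdf <- function(x, ...) {
  graphics::plot(x$scl, x$f_h, type = "s", xlab = "SCL (cm)",
                 ylab = expression(F[H](SCL)), ylim = c(0, 1), ...)
}

#' Build F_H input records from classified tracks
#'
#' Combines \code{\link{classify_tracks}} output with imputed daily sizes:
#' the observed SCL range [s0, s1] is taken over the days of the non-U
#' segments, and sb is the SCL at the DH breakpoint. Tracks without size
#' information, unreliable tracks and HD tracks are dropped.
#'
#' @param classified output of \code{\link{classify_tracks}}.
#' @param tracks track data.frame with daily \code{scl}.
#' @return data.frame id, klass, s0, s1, sb ready for
#'   \code{\link{estimate_f_h}}.
#' @export
f_h_records <- function(classified, tracks) {
  rows <- lapply(seq_len(nrow(classified)), function(i) {
    cl <- classified[i, ]
    if (!cl$klass %in% c("D_only", "H_only", "DH")) return(NULL)
    d <- tracks[tracks$id == cl$id, , drop = FALSE]
    if (!"scl" %in% names(d) || all(is.na(d$scl))) return(NULL)
    valid_days <- rep(FALSE, nrow(d))
    if (!is.na(cl$seg1_klass) && cl$seg1_klass != "U")
      valid_days <- valid_days | (d$date >= cl$seg1_start & d$date <= cl$seg1_end)
    if (!is.na(cl$seg2_klass) && cl$seg2_klass != "U")
      valid_days <- valid_days | (d$date >= cl$seg2_start & d$date <= cl$seg2_end)
    scl <- d$scl[valid_days]
    if (!length(scl)) return(NULL)
    data.frame(id = cl$id, klass = cl$klass,
               s0 = min(scl, na.rm = TRUE), s1 = max(scl, na.rm = TRUE),
               sb = cl$breakpoint_scl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Seasonality of homing onsets: monthly histogram and Rayleigh test
#'
#' Maps breakpoint dates to angles \code{2 pi doy / 365.25} and tests
#' uniformity over the year with the Rayleigh test. With resultant length
#' Rbar and Z = n Rbar^2, the p-value uses the standard second-order
#' approximation \code{p = exp(-Z) [1 + (2Z - Z^2) / (4n)]}, clipped to
#' [0, 1]. The approximation needs at least 5 dates.
#'
#' @param dates Date vector of breakpoint dates (n >= 5).
#' @return list: monthly (12 counts), resultant_length, Z, p_value, n.
#' @export
breakpoint_seasonality <- function(dates) {
  dates <- as.Date(dates[!is.na(dates)])
  n <- length(dates)
  if (n < 5) stop("Rayleigh approximation needs at least 5 dates; got ", n)
  ang <- 2 * pi * .doy(dates) / 365.25
  C <- mean(cos(ang)); S <- mean(sin(ang))
  R <- sqrt(C^2 + S^2)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n))
  p <- min(max(p, 0), 1)
  monthly <- tabulate(as.integer(format(dates, "%m")), nbins = 12L)
  names(monthly) <- month.abb
  list(monthly = monthly, resultant_length = R, Z = Z, p_value = p, n = n)
}
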
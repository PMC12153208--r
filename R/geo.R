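#' @keywords internal
"_PACKAGE"

# Local equirectangular metric. All displacement <-> degree conversions in the
# package go through these two helpers so that simulator and estimator use the
# same discretization.

#' Earth radius used throughout (m)
#' @export
EARTH_RADIUS_M <- 6371000

#' Meters per degree of longitude at a given latitude
#'
#' Local equirectangular metric: one degree of longitude spans
#' \code{(pi/180) * R * cos(lat)} meters at latitude \code{lat}, with
#' \code{R = 6371000} m. Used for all conversions between angular displacements
#' and metric velocities; the error relative to a proper geodesic is below
#' 0.2\% for daily displacements, far below Argos positioning noise.
#'
#' @param lat latitude in degrees North (vectorized).
#' @return meters per degree longitude.
#' @export
m_per_deg_lon <- function(lat) (pi / 180) * EARTH_RADIUS_M * cos(lat * pi / 180)

#' Meters per degree of latitude
#' @return meters per degree latitude (constant on the sphere).
#' @export
m_per_deg_lat <- function() (pi / 180) * EARTH_RADIUS_M

#' Unwrap a longitude series across the antimeridian
#'
#' Makes a per-track longitude series continuous by removing 360-degree jumps:
#' each successive difference is brought into (-180, 180]. The first value is
#' kept as given, so e.g. 179.9 followed by -179.9 unwraps to 179.9, 180.1.
#'
#' @param lon numeric vector of longitudes in degrees East.
#' @return continuous (unwrapped) longitudes; \code{unwrap_lon(wrap_lon(x))}
#'   recovers \code{x} up to a multiple of 360 anchored at the first element.
#' @export
unwrap_lon <- function(lon) {
  if (length(lon) < 2) return(lon)
  d <- diff(lon)
  d <- d - 360 * round(d / 360)
  cumsum(c(lon[1], d))
}

#' Wrap longitudes into [-180, 180)
#' @param lon numeric vector of longitudes.
#' @export
wrap_lon <- function(lon) {
  w <- (lon + 180) %% 360 - 180
  w
}

# map query longitudes into the continuous range covered by a grid axis
.lon_into_range <- function(lon, lo, hi) {
  k <- (lon < lo) | (lon > hi)
  if (any(k)) {
    shift <- 360 * ceiling((lo - lon) / 360)
    cand <- lon + shift
    bad <- cand > hi & k
    lon[k] <- cand[k]
    # if still outside after shifting up, try shifting down from above
    if (any(bad)) lon[bad] <- lon[bad] - 360 * ceiling((lon[bad] - hi) / 360)
  }
  lon
}

.doy <- function(dates) as.POSIXlt(dates)$yday + 1L
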
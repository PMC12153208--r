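# Daily-track data model and I/O.
#
# A track table is a plain data.frame with one row per (id, day): columns
# id, date (Date, the 12:00 UTC daily fix), lat, lon (unwrapped, continuous
# across the antimeridian), and optionally group, release_scl plus any
# computed columns (vg_*, vco_*, vsto_*, scl, u_dc, v_dc, x_dc_km, y_dc_km).
# Gaps in the calendar split a track into independent blocks; velocities are
# never computed across a gap.

.required_cols <- c("id", "date", "lat", "lon")

# integer block label per row: consecutive calendar days share a block
.block_id <- function(dates) {
  if (length(dates) == 0) return(integer(0))
  cumsum(c(1L, as.integer(diff(as.integer(dates)) != 1L)))
}

#' Read daily tracks from a CSV file
#'
#' Expects one row per individual per day with columns \code{id},
#' \code{date} (ISO-8601), \code{lat}, \code{lon} and, optionally,
#' \code{group} and \code{release_scl}. Rows with unparseable dates or
#' missing coordinates are dropped with a warning; duplicate (id, date)
#' pairs are an error. Longitudes are unwrapped per track so that series
#' crossing the antimeridian stay continuous.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping the canonical names
#'   (\code{id}, \code{date}, \code{lat}, \code{lon}, \code{group},
#'   \code{release_scl}) to the column names actually present in the file.
#' @return a track data.frame ordered by (id, date), with \code{lon} unwrapped.
#' @export
read_tracks <- function(path, schema = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw)) stop("schema column not found in file: ", src)
      names(raw)[names(raw) == src] <- canon
    }
  }
  miss <- setdiff(.required_cols, names(raw))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  dates <- suppressWarnings(as.Date(raw$date))
  bad_date <- is.na(dates)
  if (any(bad_date)) {
    warning(sum(bad_date), " row(s) with malformed dates dropped")
  }
  bad_pos <- !bad_date & (is.na(raw$lat) | is.na(raw$lon))
  if (any(bad_pos)) {
    message(sum(bad_pos), " row(s) with missing lat/lon dropped")
  }
  keep <- !bad_date & !bad_pos
  tr <- data.frame(
    id = as.character(raw$id[keep]),
    date = dates[keep],
    lat = as.numeric(raw$lat[keep]),
    lon = as.numeric(raw$lon[keep]),
    stringsAsFactors = FALSE
  )
  if ("group" %in% names(raw)) tr$group <- as.character(raw$group[keep])
  if ("release_scl" %in% names(raw)) tr$release_scl <- as.numeric(raw$release_scl[keep])
  computed <- c("vg_u", "vg_v", "vco_u", "vco_v", "vsto_u", "vsto_v",
                "scl", "u_dc", "v_dc", "x_dc_km", "y_dc_km")
  for (cc in intersect(computed, names(raw))) tr[[cc]] <- as.numeric(raw[[cc]][keep])
  dup <- tr$id[duplicated(tr[c("id", "date")])]
  if (length(dup)) stop("duplicate (id, date) rows for id(s): ",
                        paste(unique(dup), collapse = ", "))
  # preserve per-id original order, then sort by date within id (stable)
  tr <- tr[order(match(tr$id, unique(tr$id)), tr$date), , drop = FALSE]
  rownames(tr) <- NULL
  tr$lon <- stats::ave(tr$lon, tr$id, FUN = unwrap_lon)
  validate_tracks(tr)
  tr
}

#' Validate a track table
#'
#' Checks the structural invariants of the daily-track model: required
#' columns, latitude range, strictly increasing dates within each id, and
#' daily longitude steps below 5 degrees (a blunder guard).
#'
#' @param tracks track data.frame.
#' @return the input, invisibly; warns on suspicious longitude steps.
#' @export
validate_tracks <- function(tracks) {
  miss <- setdiff(.required_cols, names(tracks))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (any(tracks$lat < -90 | tracks$lat > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
  for (d in split(tracks, tracks$id)) {
    if (is.unsorted(d$date, strictly = TRUE)) stop("dates not strictly increasing for id ", d$id[1])
    dl <- abs(diff(d$lon)) / as.integer(diff(d$date))
    if (any(dl >= 5, na.rm = TRUE)) {
      warning("daily longitude step >= 5 degrees for id ", d$id[1])
    }
  }
  invisible(tracks)
}

#' Write a track table to CSV
#'
#' Emits the same schema read by \code{\link{read_tracks}} plus any computed
#' columns present (velocities, matched fields, DC series, size).
#'
#' @param tracks track data.frame.
#' @param path output path.
#' @param wrap if TRUE (default), longitudes are wrapped back into
#'   [-180, 180) on output.
#' @export
write_tracks <- function(tracks, path, wrap = TRUE) {
  out <- tracks
  if (wrap) out$lon <- wrap_lon(out$lon)
  out$date <- format(out$date)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Midnight positions by linear interpolation
#'
#' Positions at 0:00 UTC are estimated as the arithmetic mean (in latitude
#' and unwrapped longitude independently) of the two adjacent 12:00 UTC
#' fixes. Only interior midnights of each contiguous block exist: a block of
#' n consecutive days yields n - 1 midnights.
#'
#' @param tracks track data.frame.
#' @return data.frame with columns id, date (the calendar day whose 0:00 UTC
#'   the row describes), lat, lon.
#' @export
interpolate_midnight <- function(tracks) {
  pieces <- lapply(split(tracks, tracks$id), function(d) {
    d <- d[order(d$date), , drop = FALSE]
    blk <- .block_id(d$date)
    res <- lapply(split(seq_len(nrow(d)), blk), function(ix) {
      if (length(ix) < 2) return(NULL)
      i <- ix[-length(ix)]; j <- ix[-1]
      data.frame(
        id = d$id[i],
        date = d$date[j],              # midnight at 0:00 of day j
        lat = (d$lat[i] + d$lat[j]) / 2,
        lon = (d$lon[i] + d$lon[j]) / 2,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Daily-mean velocity over ground
#'
#' Computes the daily-mean (0:00 to 24:00 UTC) velocity over ground from
#' centered finite differences of tracked positions and attaches it to the
#' 12:00 UTC record of the day. In the default \code{"midnight"} method the
#' day's velocity is the displacement between the bracketing interpolated
#' midnights, which equals the centered difference of the 12:00 fixes one
#' day apart divided by two days; it is defined only on interior days of a
#' block (both bracketing midnights must exist). The \code{"direct"} method
#' is the forward difference between successive 12:00 fixes attached to the
#' first day. Degrees are converted to meters with the local equirectangular
#' metric at the mean latitude of the two endpoints.
#'
#' @param tracks track data.frame.
#' @param method \code{"midnight"} (daily mean over 0:00-24:00, the default)
#'   or \code{"direct"} (12:00-to-12:00 forward difference).
#' @return the input with columns \code{vg_u}, \code{vg_v} (m/s) added; days
#'   without both bracketing positions get NA, never zero.
#' @export
velocity_over_ground <- function(tracks, method = c("midnight", "direct")) {
  method <- match.arg(method)
  tracks <- tracks[order(match(tracks$id, unique(tracks$id)), tracks$date), , drop = FALSE]
  tracks$vg_u <- NA_real_
  tracks$vg_v <- NA_real_
  for (ix_id in split(seq_len(nrow(tracks)), tracks$id)) {
    d <- tracks[ix_id, , drop = FALSE]
    blk <- .block_id(d$date)
    for (ix in split(seq_along(ix_id), blk)) {
      n <- length(ix)
      if (n < 2) next
      rows <- ix_id[ix]
      lat <- d$lat[ix]; lon <- d$lon[ix]
      if (method == "midnight") {
        if (n < 3) next
        # midnights: m[k] at 0:00 of day k (k = 2..n), position (X[k-1]+X[k])/2
        m_lat <- (lat[-n] + lat[-1]) / 2
        m_lon <- (lon[-n] + lon[-1]) / 2
        # day k (k = 2..n-1) bracketed by midnights k-1 and k (0-based in m)
        i <- seq_len(n - 2L)
        dlat <- m_lat[i + 1L] - m_lat[i]
        dlon <- m_lon[i + 1L] - m_lon[i]
        mlat <- (m_lat[i + 1L] + m_lat[i]) / 2
        tracks$vg_u[rows[i + 1L]] <- dlon * m_per_deg_lon(mlat) / 86400
        tracks$vg_v[rows[i + 1L]] <- dlat * m_per_deg_lat() / 86400
      } else {
        i <- seq_len(n - 1L)
        mlat <- (lat[i] + lat[i + 1L]) / 2
        tracks$vg_u[rows[i]] <- (lon[i + 1L] - lon[i]) * m_per_deg_lon(mlat) / 86400
        tracks$vg_v[rows[i]] <- (lat[i + 1L] - lat[i]) * m_per_deg_lat() / 86400
      }
    }
  }
  tracks
}
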
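# Gridded daily surface vector fields (Eulerian current + surface Stokes
# drift) and along-track sampling.
#
# A field_set stores node-registered values on regular ascending lat/lon
# axes. Longitudes are kept continuous over the basin (e.g. 120..250 degE)
# so the antimeridian never introduces a seam; queries are shifted by
# multiples of 360 into the grid range. Land is represented by NA cells and
# propagates as missing; bilinear stencils touching 1-3 masked nodes are
# renormalized over the valid nodes.

#' Construct a gridded field set
#'
#' @param lat,lon regular, strictly ascending axes (degrees); values are at
#'   the nodes.
#' @param time vector of Dates for time-varying fields, or NULL for a static
#'   (time-invariant) field set.
#' @param u_co,v_co,u_sto,v_sto arrays of dim (nlat, nlon) for static sets or
#'   (nlat, nlon, ntime) otherwise: Eulerian surface current and surface
#'   Stokes drift components in m/s. NA marks masked (land) cells.
#' @param stokes_anom optional data.frame (date, du, dv): a basin-wide daily
#'   Stokes-drift anomaly added to the gridded Stokes values on sampling.
#'   Represents the synoptic (wave-weather) part of the Stokes drift without
#'   storing a full time-varying grid; dates not listed sample as missing.
#' @return an object of class \code{field_set}.
#' @export
field_set <- function(lat, lon, u_co, v_co, u_sto, v_sto, time = NULL,
                      stokes_anom = NULL) {
  .check_axis(lat, "lat"); .check_axis(lon, "lon")
  dims <- if (is.null(time)) c(length(lat), length(lon)) else
    c(length(lat), length(lon), length(time))
  for (nm in c("u_co", "v_co", "u_sto", "v_sto")) {
    a <- get(nm)
    if (!isTRUE(all.equal(dim(a), dims, check.attributes = FALSE)) &&
        !identical(as.integer(dim(a)), as.integer(dims)))
      stop(nm, " has wrong dimensions")
    if (any(is.infinite(a))) stop(nm, " contains non-finite unmasked values")
  }
  if (!is.null(stokes_anom))
    stopifnot(all(c("date", "du", "dv") %in% names(stokes_anom)))
  structure(list(lat = lat, lon = lon, time = time,
                 u_co = u_co, v_co = v_co, u_sto = u_sto, v_sto = v_sto,
                 stokes_anom = stokes_anom),
            class = "field_set")
}

.check_axis <- function(ax, name) {
  if (length(ax) < 2 || is.unsorted(ax, strictly = TRUE))
    stop(name, " axis must be strictly ascending")
  st <- diff(ax)
  if (max(st) - min(st) > 1e-6) stop(name, " axis must be uniform within 1e-6 degree")
}

#' @export
print.field_set <- function(x, ...) {
  cat("field_set:", length(x$lat), "x", length(x$lon), "nodes,",
      if (is.null(x$time)) "static" else paste(length(x$time), "days"), "\n")
  cat("  lat", min(x$lat), "..", max(x$lat), " lon", min(x$lon), "..", max(x$lon), "\n")
  invisible(x)
}

#' Average sub-daily field slices to daily means
#'
#' Arithmetic mean over all slices whose timestamp falls within
#' [0:00, 24:00) UTC of each day, per component and cell. Days with no
#' slices are dropped with a message.
#'
#' @param times POSIXct timestamps of the slices (UTC).
#' @param values array (nlat, nlon, nslices).
#' @return list with \code{dates} (Date) and \code{values}
#'   (nlat, nlon, ndays).
#' @export
daily_average <- function(times, values) {
  stopifnot(length(times) == dim(values)[3])
  day <- as.Date(times, tz = "UTC")
  days <- sort(unique(day))
  out <- array(NA_real_, c(dim(values)[1:2], length(days)))
  for (k in seq_along(days)) {
    sl <- which(day == days[k])
    out[, , k] <- apply(values[, , sl, drop = FALSE], c(1, 2), mean)
  }
  list(dates = days, values = out)
}

# core bilinear sampler on one (nlat, nlon) matrix; vectorized over queries.
# masked nodes (NA) get weight 0 and remaining weights renormalized; all four
# masked -> NA.
.bilinear <- function(mat, lat_ax, lon_ax, lat, lon) {
  n <- length(lat)
  dlat <- lat_ax[2] - lat_ax[1]; dlon <- lon_ax[2] - lon_ax[1]
  fi <- (lat - lat_ax[1]) / dlat
  fj <- (lon - lon_ax[1]) / dlon
  i0 <- pmin.int(pmax.int(floor(fi), 0), length(lat_ax) - 2L)
  j0 <- pmin.int(pmax.int(floor(fj), 0), length(lon_ax) - 2L)
  out_of_hull <- fi < 0 | fi > length(lat_ax) - 1L | fj < 0 | fj > length(lon_ax) - 1L
  if (any(out_of_hull, na.rm = TRUE)) {
    bad <- which(out_of_hull)[1]
    stop(sprintf("point outside grid hull: lat=%.4f lon=%.4f", lat[bad], lon[bad]))
  }
  ti <- fi - i0; tj <- fj - j0
  nr <- length(lat_ax)
  idx <- function(i, j) i + 1L + nr * j     # 1-based linear index into mat
  v00 <- mat[idx(i0,      j0)]
  v10 <- mat[idx(i0 + 1L, j0)]
  v01 <- mat[idx(i0,      j0 + 1L)]
  v11 <- mat[idx(i0 + 1L, j0 + 1L)]
  w00 <- (1 - ti) * (1 - tj); w10 <- ti * (1 - tj)
  w01 <- (1 - ti) * tj;       w11 <- ti * tj
  vals <- cbind(v00, v10, v01, v11)
  w <- cbind(w00, w10, w01, w11)
  w[is.na(vals)] <- 0
  vals[is.na(vals)] <- 0
  tot <- rowSums(w)
  res <- rowSums(vals * w) / tot
  res[tot == 0] <- NA_real_
  res
}

.time_slice <- function(fields, comp, date) {
  a <- fields[[comp]]
  if (is.null(fields$time)) {
    if (length(dim(a)) == 3L) a[, , 1] else a
  } else {
    k <- match(as.Date(date), fields$time)
    if (is.na(k)) NULL else a[, , k]
  }
}

#' Sample a field set by bilinear interpolation
#'
#' Standard bilinear weights over the four surrounding grid nodes at the
#' query position, on the daily slice matching \code{date}. Masked (NA)
#' nodes get zero weight with the remaining weights renormalized; a point
#' whose four nodes are all masked returns NA. Querying outside the grid
#' hull is an error naming the offending point.
#'
#' @param fields a \code{field_set}.
#' @param date a Date (scalar); ignored for static field sets.
#' @param lat,lon query coordinates (vectors of equal length).
#' @param what \code{"current"} or \code{"stokes"}.
#' @return data.frame with columns \code{u}, \code{v} (m/s).
#' @export
sample_bilinear <- function(fields, date, lat, lon, what = c("current", "stokes")) {
  what <- match.arg(what)
  lon <- .lon_into_range(lon, min(fields$lon), max(fields$lon))
  comps <- if (what == "current") c("u_co", "v_co") else c("u_sto", "v_sto")
  mu <- .time_slice(fields, comps[1], date)
  mv <- .time_slice(fields, comps[2], date)
  if (is.null(mu)) return(data.frame(u = rep(NA_real_, length(lat)),
                                     v = rep(NA_real_, length(lat))))
  u <- .bilinear(mu, fields$lat, fields$lon, lat, lon)
  v <- .bilinear(mv, fields$lat, fields$lon, lat, lon)
  if (what == "stokes" && !is.null(fields$stokes_anom)) {
    k <- match(as.Date(date), fields$stokes_anom$date)
    if (is.na(k)) {
      u[] <- NA_real_; v[] <- NA_real_
    } else {
      u <- u + fields$stokes_anom$du[k]
      v <- v + fields$stokes_anom$dv[k]
    }
  }
  data.frame(u = u, v = v)
}

#' Match environmental fields onto a track table
#'
#' For each daily record, samples the daily-mean Eulerian current and Stokes
#' drift at the 12:00 UTC position by bilinear interpolation, filling the
#' columns \code{vco_u}, \code{vco_v}, \code{vsto_u}, \code{vsto_v}. Days
#' absent from the field time axis stay missing.
#'
#' @param tracks track data.frame.
#' @param fields a \code{field_set}.
#' @return the track table with matched columns; attribute
#'   \code{"match_counts"} holds c(matched, unmatched). Warns if no day could
#'   be matched.
#' @export
match_fields <- function(tracks, fields) {
  n <- nrow(tracks)
  tracks$vco_u <- tracks$vco_v <- tracks$vsto_u <- tracks$vsto_v <- NA_real_
  inside <- tracks$lat >= min(fields$lat) & tracks$lat <= max(fields$lat)
  qlon <- .lon_into_range(tracks$lon, min(fields$lon), max(fields$lon))
  inside <- inside & qlon >= min(fields$lon) & qlon <= max(fields$lon)
  udates <- unique(tracks$date)
  for (k in seq_along(udates)) {
    date <- udates[k]
    ix <- which(tracks$date == date & inside)
    if (!length(ix)) next
    cur <- sample_bilinear(fields, date, tracks$lat[ix], tracks$lon[ix], "current")
    sto <- sample_bilinear(fields, date, tracks$lat[ix], tracks$lon[ix], "stokes")
    tracks$vco_u[ix] <- cur$u; tracks$vco_v[ix] <- cur$v
    tracks$vsto_u[ix] <- sto$u; tracks$vsto_v[ix] <- sto$v
  }
  matched <- sum(!is.na(tracks$vco_u) & !is.na(tracks$vsto_u))
  if (matched == 0 && n > 0) warning("no track day could be matched to the fields")
  attr(tracks, "match_counts") <- c(matched = matched, unmatched = n - matched)
  tracks
}

#' Box statistics of sampled vectors
#'
#' Aggregates point vectors into regular boxes (default 5 x 5 degrees):
#' component-wise mean vector, standard deviation of the norm of the
#' individual vectors, and sample count per box. Empty boxes are absent from
#' the output.
#'
#' @param samples data.frame with columns lat, lon, u, v; rows with missing
#'   u or v are dropped.
#' @param box box edge length in degrees (default 5).
#' @param origin lower-left corner the boxes are anchored to
#'   (default c(0, 0)).
#' @return data.frame: lat0, lon0 (box lower-left), mean_u, mean_v, sd_norm, n.
#' @export
box_statistics <- function(samples, box = 5, origin = c(0, 0)) {
  ok <- !is.na(samples$u) & !is.na(samples$v)
  s <- samples[ok, , drop = FALSE]
  if (nrow(s) == 0) return(data.frame(lat0 = numeric(0), lon0 = numeric(0),
                                      mean_u = numeric(0), mean_v = numeric(0),
                                      sd_norm = numeric(0), n = integer(0)))
  lat0 <- origin[1] + box * floor((s$lat - origin[1]) / box)
  lon0 <- origin[2] + box * floor((s$lon - origin[2]) / box)
  key <- paste(lat0, lon0, sep = "_")
  agg <- lapply(split(seq_len(nrow(s)), key), function(ix) {
    nrm <- sqrt(s$u[ix]^2 + s$v[ix]^2)
    data.frame(lat0 = lat0[ix[1]], lon0 = lon0[ix[1]],
               mean_u = mean(s$u[ix]), mean_v = mean(s$v[ix]),
               sd_norm = if (length(ix) > 1) stats::sd(nrm) else 0,
               n = length(ix))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$lat0, out$lon0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a field set to a long-format CSV
#'
#' One row per (time, lat, lon) node with CF-style variable names
#' (\code{uo}, \code{vo} for the current, \code{vsdx}, \code{vsdy} for the
#' Stokes drift). Plain-text stand-in for the NetCDF layout of the CMEMS
#' reanalysis products.
#'
#' @param fields a \code{field_set}.
#' @param path output CSV path.
#' @export
write_fields <- function(fields, path) {
  nt <- if (is.null(fields$time)) 1L else length(fields$time)
  grid <- expand.grid(lat = fields$lat, lon = fields$lon,
                      t = seq_len(nt), KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(
    time = if (is.null(fields$time)) "static" else format(fields$time[grid$t]),
    lat = grid$lat, lon = grid$lon,
    uo = as.vector(fields$u_co), vo = as.vector(fields$v_co),
    vsdx = as.vector(fields$u_sto), vsdy = as.vector(fields$v_sto)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(fields$stokes_anom)) {
    an <- fields$stokes_anom
    an$date <- format(an$date)
    utils::write.csv(an, .anom_path(path), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

.anom_path <- function(path) sub("(\\.[^.]+)?$", "_stokes_anom.csv", path)

#' Read a field set written by \code{write_fields}
#' @param path CSV path.
#' @return a \code{field_set}.
#' @export
read_fields <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  static <- identical(unique(df$time), "static")
  time <- if (static) NULL else sort(unique(as.Date(df$time)))
  nt <- if (static) 1L else length(time)
  dims <- c(length(lat), length(lon), nt)
  ord <- order(if (static) rep(1L, nrow(df)) else match(as.Date(df$time), time),
               match(df$lon, lon), match(df$lat, lat))
  shape <- function(x) {
    a <- array(x[ord], dims)
    if (static) a[, , 1] else a
  }
  anom <- NULL
  ap <- .anom_path(path)
  if (file.exists(ap)) {
    anom <- utils::read.csv(ap, stringsAsFactors = FALSE)
    anom$date <- as.Date(anom$date)
  }
  field_set(lat, lon, time = time,
            u_co = shape(df$uo), v_co = shape(df$vo),
            u_sto = shape(df$vsdx), v_sto = shape(df$vsdy),
            stokes_anom = anom)
}
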
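# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# a one-id daily track from coordinate vectors
make_track <- function(lat, lon, id = "t1", start = as.Date("2005-03-01"),
                       release_scl = NA_real_) {
  data.frame(id = id, date = start + seq_along(lat) - 1L,
             lat = lat, lon = lon, release_scl = release_scl,
             stringsAsFactors = FALSE)
}

# field with components linear in lat and lon (bilinear sampling is exact on
# these); u = a0 + a_lat*lat + a_lon*lon etc.
make_linear_field <- function(lat = seq(20, 55, 1), lon = seq(120, 250, 1),
                              cu = c(0.1, 0.002, -0.001), cv = c(0, 0.001, 0.0005),
                              su = c(0.02, 0.0005, 0), sv = c(-0.01, 0, 0.0002)) {
  g <- expand.grid(lat = lat, lon = lon)
  lin <- function(co) matrix(co[1] + co[2] * g$lat + co[3] * g$lon, nrow = length(lat))
  field_set(lat, lon, u_co = lin(cu), v_co = lin(cv),
            u_sto = lin(su), v_sto = lin(sv))
}

# constant-everywhere field
make_const_field <- function(vco = c(0.2, 0), vsto = c(0.05, 0.05),
                             lat = seq(20, 55, 1), lon = seq(120, 250, 1)) {
  m <- function(x) matrix(x, length(lat), length(lon))
  field_set(lat, lon, u_co = m(vco[1]), v_co = m(vco[2]),
            u_sto = m(vsto[1]), v_sto = m(vsto[2]))
}

# exhaustive O(n^2) breakpoint oracle: recompute both segment SSEs per split
oracle_breakpoint <- function(u) {
  n <- length(u)
  if (n < 2) return(NA_integer_)
  sse <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) 0 else sum((x - mean(x))^2)
  }
  costs <- vapply(seq_len(n - 1L), function(b)
    sse(u[seq_len(b)]) + sse(u[seq.int(b + 1L, n)]), numeric(1))
  which.min(costs)
}

# daily zonal DC-velocity series wrapped as a minimal classified-track input
make_u_series <- function(u, id = "s1", start = as.Date("2006-01-01")) {
  data.frame(id = id, date = start + seq_along(u) - 1L, u_dc = u,
             stringsAsFactors = FALSE)
}

# von Mises sampler (Best & Fisher rejection), used as an independent
# concentration oracle for the Rayleigh test power check
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}
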
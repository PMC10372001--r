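# Independent oracles and small builders shared across the suite. The
# oracles deliberately use naive formulations (explicit loops, closed
# forms) so they share no code path with the implementation they check.

# spherical quadrilateral area, closed form, ha
oracle_cell_area_ha <- function(lat_lo, lat_hi, lon_lo, lon_hi, R_km = 6371) {
  R_km^2 * ((lon_hi - lon_lo) * pi / 180) *
    (sin(lat_hi * pi / 180) - sin(lat_lo * pi / 180)) * 100
}

# cropland-weighted national rate by an explicit cell x country triple loop
oracle_national_rate <- function(dep, crop, shares) {
  iso <- dimnames(shares)[[3]]
  out <- setNames(numeric(length(iso)), iso)
  for (k in seq_along(iso)) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(dep))) for (j in seq_len(ncol(dep))) {
      w <- crop[i, j] * shares[i, j, k]
      num <- num + dep[i, j] * w
      den <- den + w
    }
    out[k] <- if (den > 0) num / den else NaN
  }
  out
}

# per-cell OLS by the normal equations, explicit solve per cell
oracle_ols <- function(dep_list, emis_list) {
  dims <- dim(dep_list[[1]])
  b0 <- b1 <- matrix(NA_real_, dims[1], dims[2])
  n <- length(dep_list)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    x <- vapply(emis_list, function(m) m[i, j], numeric(1))
    y <- vapply(dep_list, function(m) m[i, j], numeric(1))
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    b0[i, j] <- beta[1]; b1[i, j] <- beta[2]
  }
  list(beta0 = b0, beta1 = b1)
}

# percentile by explicit sort-and-interpolate (index 1 + p(n-1))
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- 1 + p * (n - 1)
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small co-registered field builder
mkfield <- function(g, v, units = "kg N ha-1 yr-1", year = NA) {
  annual_field(g, matrix(v, length(g$lat), length(g$lon)), units, year)
}

# tiny exactly-affine world: dep = a + b * emis, emis linear in year
tiny_affine_world <- function(nlat = 3, nlon = 4, seed = 7) {
  set.seed(seed)
  g <- grid_spec(seq(10, 10 + 2 * (nlat - 1), by = 2),
                 seq(-30, -30 + 2 * (nlon - 1), by = 2))
  a <- matrix(runif(nlat * nlon, 1, 4), nlat, nlon)
  b <- matrix(runif(nlat * nlon, 0.2, 0.9), nlat, nlon)
  e0 <- matrix(runif(nlat * nlon, 5, 15), nlat, nlon)
  e1 <- matrix(runif(nlat * nlon, 0.02, 0.1), nlat, nlon)
  emis_at <- function(y) e0 + e1 * (y - 1970)
  dep_at <- function(y) a + b * emis_at(min(y, 2018))
  anchor_years <- c(1960, 1970, 1980, 1990, 1997:2013)
  anchors <- setNames(lapply(anchor_years, function(y)
    annual_field(g, dep_at(y), "kg N ha-1 yr-1", y)), anchor_years)
  emissions <- setNames(lapply(1970:2018, function(y)
    annual_field(g, emis_at(y), "kg N", y)), 1970:2018)
  truth <- setNames(lapply(1961:2020, function(y)
    annual_field(g, dep_at(y), "kg N ha-1 yr-1", y)), 1961:2020)
  list(grid = g, a = a, b = b, anchors = anchors, emissions = emissions,
       truth = truth, emis_at = emis_at, dep_at = dep_at)
}
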
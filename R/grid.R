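# Regular lat/lon grid data model, spherical cell areas, conservative
# regridding and country masks.

EARTH_RADIUS_KM <- 6371

#' Define a regular latitude/longitude grid
#'
#' A grid is described by its cell-center coordinates; spacing must be
#' uniform in each dimension. Latitudes are stored ascending; longitudes are
#' normalized to \[-180, 180) so grids crossing the dateline are supported.
#'
#' @param lat numeric vector of latitude cell centers (degrees), regular step.
#' @param lon numeric vector of longitude cell centers (degrees), regular step.
#' @param lat_step,lon_step explicit cell sizes in degrees; required only
#'   when a dimension has a single center (the step cannot be inferred), in
#'   which case they default to 1.
#' @return An object of class `grid_spec` with elements `lat`, `lon`,
#'   `lat_step`, `lon_step`.
#' @examples
#' g <- grid_spec(lat = seq(-89.5, 89.5, by = 1), lon = seq(-179.5, 179.5, by = 1))
#' @export
grid_spec <- function(lat, lon, lat_step = NULL, lon_step = NULL) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (length(lat) < 1L || length(lon) < 1L)
    stop("grid must have at least one cell in each dimension")
  step_of <- function(x, what) {
    if (length(x) == 1L) return(NA_real_)
    d <- diff(x)
    if (any(abs(d - d[1]) > 1e-9))
      stop(what, " spacing is not uniform (tolerance 1e-9 degrees)")
    d[1]
  }
  inferred_lat <- step_of(lat, "latitude")
  inferred_lon <- step_of(lon, "longitude")
  lat_step <- if (!is.null(lat_step)) as.numeric(lat_step) else inferred_lat
  lon_step <- if (!is.null(lon_step)) as.numeric(lon_step) else inferred_lon
  if (!is.na(lat_step) && lat_step < 0) { lat <- rev(lat); lat_step <- -lat_step }
  if (is.na(lat_step)) lat_step <- 1  # single row: nominal 1 degree cell
  if (is.na(lon_step)) lon_step <- 1
  if (lat[1] - lat_step / 2 < -90 - 1e-9 || lat[length(lat)] + lat_step / 2 > 90 + 1e-9)
    stop("latitude cell edges extend past the poles")
  if (length(lon) * abs(lon_step) > 360 + 1e-9)
    stop("longitude span exceeds 360 degrees")
  lon_norm <- ((lon + 180) %% 360) - 180
  structure(list(lat = lat, lon = lon, lon_norm = lon_norm,
                 lat_step = lat_step, lon_step = abs(lon_step)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.4g deg x %.4g deg\n",
              length(x$lat), length(x$lon), x$lat_step, x$lon_step))
  cat(sprintf("  lat [%.4g, %.4g]  lon [%.4g, %.4g]\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...)
  sprintf("%dx%d grid", length(x$lat), length(x$lon))

grids_identical <- function(a, b, tol = 1e-9) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    all(abs(a$lat - b$lat) < tol) && all(abs(a$lon - b$lon) < tol)
}

#' A per-cell value layer for one year
#'
#' Wraps a `nlat x nlon` value matrix with its grid, year and units. Units
#' drive validation: fraction fields must lie in \[0, 1\], area fields must
#' be non-negative.
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix, `length(grid$lat)` rows x `length(grid$lon)`
#'   columns; `NA` marks missing cells.
#' @param units one of `"kg N ha-1 yr-1"` (deposition rate), `"ha"` (area),
#'   `"fraction"`, `"kg N"` (emission mass), `"mm"` (precipitation).
#' @param year integer year or `NA` for year-independent layers.
#' @return An object of class `annual_field`.
#' @export
annual_field <- function(grid, values, units, year = NA_integer_) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != length(grid$lat) || ncol(values) != length(grid$lon))
    stop(sprintf("values shape %dx%d does not match grid %dx%d",
                 nrow(values), ncol(values), length(grid$lat), length(grid$lon)))
  units <- match.arg(units, c("kg N ha-1 yr-1", "ha", "fraction", "kg N", "mm"))
  finite <- values[is.finite(values)]
  if (units == "fraction" && length(finite) &&
      (min(finite) < -1e-12 || max(finite) > 1 + 1e-12))
    stop("fraction field has values outside [0, 1]")
  if (units == "ha" && length(finite) && min(finite) < -1e-12)
    stop("area field has negative values")
  structure(list(grid = grid, values = values, units = units,
                 year = as.integer(year)),
            class = "annual_field")
}

#' @export
print.annual_field <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("annual_field [%s] %s year=%s  range [%.4g, %.4g], %d NA\n",
              x$units, format(x$grid),
              ifelse(is.na(x$year), "-", x$year),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(!is.finite(x$values))))
  invisible(x)
}

#' Spherical cell areas of a grid
#'
#' Area of each spherical quadrilateral cell,
#' `A = R^2 * dlambda * (sin(phi_top) - sin(phi_bot))` with `R = 6371 km`,
#' expressed in hectares. Independent of longitude.
#'
#' @param grid a [grid_spec()].
#' @return An [annual_field()] with units `"ha"`.
#' @examples
#' g <- grid_spec(seq(-89.5, 89.5, 1), seq(-179.5, 179.5, 1))
#' sum(cell_areas(g)$values)  # ~ 5.1e10 ha, the sphere's surface
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  top <- grid$lat + grid$lat_step / 2
  bot <- grid$lat - grid$lat_step / 2
  if (any(top > 90 + 1e-9) || any(bot < -90 - 1e-9))
    stop("cells extend past the poles")
  top <- pmin(top, 90); bot <- pmax(bot, -90)
  dlam <- grid$lon_step * pi / 180
  # km^2 -> ha: 1 km^2 = 100 ha
  a_km2 <- EARTH_RADIUS_KM^2 * dlam * (sinpi(top / 180) - sinpi(bot / 180))
  annual_field(grid,
               matrix(a_km2 * 100, nrow = length(grid$lat),
                      ncol = length(grid$lon)),
               units = "ha")
}

# Fractional overlap weights between fine and coarse cell intervals along one
# dimension. measure(): length measure used to apportion a fine cell's value
# (sin-lat for latitude so the product measure is spherical area; degrees for
# longitude). Returns nfine x ncoarse matrix of fractions of each fine cell
# lying inside each coarse cell.
overlap_weights <- function(fine_centers, fine_step, coarse_centers, coarse_step,
                            measure = c("linear", "sinlat"), wrap = FALSE) {
  measure <- match.arg(measure)
  m <- function(x) if (measure == "sinlat") sinpi(pmin(pmax(x, -90), 90) / 180) else x
  fl <- fine_centers - fine_step / 2;  fu <- fine_centers + fine_step / 2
  shift <- if (wrap) c(-360, 0, 360) else 0
  W <- matrix(0, length(fine_centers), length(coarse_centers))
  fine_meas <- m(fu) - m(fl)
  for (s in shift) {
    cl <- coarse_centers - coarse_step / 2 + s
    cu <- coarse_centers + coarse_step / 2 + s
    for (j in seq_along(coarse_centers)) {
      lo <- pmax(fl, cl[j]); hi <- pmin(fu, cu[j])
      ov <- hi > lo
      if (any(ov))
        W[ov, j] <- W[ov, j] + (m(hi[ov]) - m(lo[ov])) / fine_meas[ov]
    }
  }
  W
}

#' Conservative fine-to-coarse regridding of an extensive field
#'
#' Each coarse cell receives the sum of fine-cell values apportioned by
#' fractional geometric (spherical-area) overlap. Only extensive quantities
#' (area in ha, emission mass in kg N) may be regridded; rates are intensive
#' and refused. Nested integer-ratio grids are the exact fast path of the
#' same computation; non-nested grids use the same fractional overlap
#' weights. A coarse cell is `NA` only if every contributing fine cell is
#' `NA`; otherwise missing contributors count as zero.
#'
#' @param fine an [annual_field()] with units `"ha"` or `"kg N"`.
#' @param coarse_grid target [grid_spec()], strictly coarser.
#' @return An [annual_field()] on `coarse_grid`, same units.
#' @export
regrid_sum <- function(fine, coarse_grid) {
  stopifnot(inherits(fine, "annual_field"), inherits(coarse_grid, "grid_spec"))
  if (!fine$units %in% c("ha", "kg N"))
    stop("regrid_sum applies to extensive quantities (ha, kg N); ",
         "got a '", fine$units, "' field - aggregate rates via national_rate")
  g <- fine$grid
  if (coarse_grid$lat_step < g$lat_step - 1e-9 ||
      coarse_grid$lon_step < g$lon_step - 1e-9)
    stop("target grid must be coarser than the source grid")
  Wlat <- overlap_weights(g$lat, g$lat_step, coarse_grid$lat,
                          coarse_grid$lat_step, measure = "sinlat")
  Wlon <- overlap_weights(g$lon_norm, g$lon_step, coarse_grid$lon_norm,
                          coarse_grid$lon_step, measure = "linear", wrap = TRUE)
  v <- fine$values
  na <- !is.finite(v)
  v[na] <- 0
  out <- t(Wlat) %*% v %*% Wlon
  # all-NA propagation: coarse cell NA iff it receives no finite contribution
  contrib <- t(Wlat) %*% (!na) %*% Wlon
  touched <- t(Wlat) %*% matrix(1, nrow(v), ncol(v)) %*% Wlon
  out[contrib == 0 & touched > 0] <- NA_real_
  annual_field(coarse_grid, out, units = fine$units, year = fine$year)
}

#' Fractional country mask on a grid
#'
#' Per-cell, per-country fractions of cell area belonging to each country.
#' Shares lie in \[0, 1\] and sum to at most 1 per cell; the remainder is
#' ocean or unassigned land.
#'
#' @param grid a [grid_spec()].
#' @param shares 3-d array `nlat x nlon x ncountry`; third dimension named
#'   with ISO3 codes.
#' @return An object of class `country_mask`.
#' @export
country_mask <- function(grid, shares) {
  stopifnot(inherits(grid, "grid_spec"), is.array(shares),
            length(dim(shares)) == 3L)
  if (dim(shares)[1] != length(grid$lat) || dim(shares)[2] != length(grid$lon))
    stop("shares array does not match grid shape")
  if (is.null(dimnames(shares)[[3]]))
    stop("shares must carry ISO3 country codes as third-dimension names")
  if (min(shares) < -1e-12 || max(shares) > 1 + 1e-12)
    stop("shares must lie in [0, 1]")
  tot <- apply(shares, c(1, 2), sum)
  if (max(tot) > 1 + 1e-9)
    stop("per-cell country shares sum to more than 1 (overlapping claims)")
  structure(list(grid = grid, countries = dimnames(shares)[[3]],
                 shares = shares),
            class = "country_mask")
}

#' @export
print.country_mask <- function(x, ...) {
  cat(sprintf("country_mask: %d countries on %s\n",
              length(x$countries), format(x$grid)))
  invisible(x)
}

# Sutherland-Hodgman clip of a polygon ring against an axis-aligned
# half-plane; ring is an n x 2 matrix (lon, lat).
clip_halfplane <- function(ring, axis, bound, keep_less) {
  if (nrow(ring) == 0L) return(ring)
  inside <- if (keep_less) ring[, axis] <= bound else ring[, axis] >= bound
  n <- nrow(ring)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- inside[i]; pj_in <- inside[j]
    if (pi_in) out <- rbind(out, ring[i, ])
    if (pi_in != pj_in) {
      t <- (bound - ring[i, axis]) / (ring[j, axis] - ring[i, axis])
      out <- rbind(out, ring[i, ] + t * (ring[j, ] - ring[i, ]))
    }
  }
  out
}

shoelace_area <- function(ring) {
  if (nrow(ring) < 3L) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Rasterize country polygons to a fractional mask
#'
#' Computes each cell's fractional coverage by each country polygon via
#' exact polygon/rectangle clipping in longitude/latitude coordinates
#' (planar degree-area fractions; adequate at the sub-degree cell sizes the
#' coverage fraction is used for). Alternatively accepts a pre-rasterized
#' integer code grid, in which case shares are 0/1.
#'
#' @param polygons named list (names = ISO3) of `n x 2` matrices of
#'   (lon, lat) ring vertices, or a single `nlat x nlon` character/factor
#'   matrix of country codes (`NA` = no country).
#' @param grid target [grid_spec()].
#' @return A [country_mask()].
#' @export
rasterize_countries <- function(polygons, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.matrix(polygons) && !is.numeric(polygons)) {
    codes <- polygons
    if (nrow(codes) != length(grid$lat) || ncol(codes) != length(grid$lon))
      stop("code grid does not match grid shape")
    iso <- sort(unique(stats::na.omit(as.character(codes))))
    shares <- array(0, dim = c(nrow(codes), ncol(codes), length(iso)),
                    dimnames = list(NULL, NULL, iso))
    for (k in seq_along(iso)) shares[, , k] <- (codes == iso[k]) & !is.na(codes)
    return(country_mask(grid, shares))
  }
  if (!is.list(polygons) || is.null(names(polygons)))
    stop("polygons must be a named list of (lon, lat) vertex matrices")
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  iso <- names(polygons)
  shares <- array(0, dim = c(nlat, nlon, length(iso)),
                  dimnames = list(NULL, NULL, iso))
  cell_deg_area <- grid$lat_step * grid$lon_step
  for (k in seq_along(iso)) {
    ring <- as.matrix(polygons[[k]])
    if (ncol(ring) != 2L || nrow(ring) < 3L)
      stop("polygon '", iso[k], "' needs at least 3 (lon, lat) vertices")
    bb_lon <- range(ring[, 1]); bb_lat <- range(ring[, 2])
    ii <- which(grid$lat + grid$lat_step / 2 > bb_lat[1] &
                grid$lat - grid$lat_step / 2 < bb_lat[2])
    jj <- which(grid$lon_norm + grid$lon_step / 2 > bb_lon[1] &
                grid$lon_norm - grid$lon_step / 2 < bb_lon[2])
    for (i in ii) for (j in jj) {
      r <- ring
      r <- clip_halfplane(r, 1, grid$lon_norm[j] - grid$lon_step / 2, FALSE)
      r <- clip_halfplane(r, 1, grid$lon_norm[j] + grid$lon_step / 2, TRUE)
      r <- clip_halfplane(r, 2, grid$lat[i] - grid$lat_step / 2, FALSE)
      r <- clip_halfplane(r, 2, grid$lat[i] + grid$lat_step / 2, TRUE)
      shares[i, j, k] <- shoelace_area(r) / cell_deg_area
    }
  }
  shares[shares > 1] <- 1  # clamp clipping round-off
  tot <- apply(shares, c(1, 2), sum)
  if (max(tot) > 1 + 1e-9)
    stop("overlapping polygons claim more than 100% of a cell")
  country_mask(grid, shares)
}
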
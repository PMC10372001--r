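# Seeded synthetic world with known ground truth: smooth deposition fields
# affine in emission, block countries, crop-type fractions on a nested finer
# grid, station records and budget tables. Used by the test suite and the
# verification script; real inputs are read through the same formats.

sub_seed <- function(seed, offset) {
  s <- (as.numeric(seed) * 1009 + offset * 9176) %% 2147483647
  as.integer(s)
}

#' Configuration of a synthetic world
#'
#' Defines the study conditions of a generated world: a coarse deposition
#' grid, an integer-ratio finer cropland grid, block countries, per-cell
#' affine emission-deposition coefficients, optional Gaussian deposition
#' noise and an anchor-availability pattern.
#'
#' @param nlat,nlon coarse (deposition) grid size; default 20 x 40 global.
#' @param refine integer refinement factor of the cropland grid (default 4).
#' @param n_countries number of block countries (default 8).
#' @param years modelled years (default 1961:2020).
#' @param sigma sd of Gaussian noise added to deposition fields (default 0).
#' @param anchor_pattern years with deposition maps available to the
#'   pipeline; default is the decadal-then-annual pattern
#'   `c(1960, 1970, 1980, 1990, 1997:2013)`.
#' @param emission_years years with emission maps (default 1970:2018).
#' @return A list of class `world_config`.
#' @export
world_config <- function(nlat = 20L, nlon = 40L, refine = 4L,
                         n_countries = 8L, years = 1961:2020, sigma = 0,
                         anchor_pattern = c(1960, 1970, 1980, 1990, 1997:2013),
                         emission_years = 1970:2018) {
  stopifnot(nlat >= 2, nlon >= 2, refine >= 1, n_countries >= 1, sigma >= 0)
  structure(list(nlat = as.integer(nlat), nlon = as.integer(nlon),
                 refine = as.integer(refine),
                 n_countries = as.integer(n_countries),
                 years = as.integer(years), sigma = sigma,
                 anchor_pattern = as.integer(anchor_pattern),
                 emission_years = as.integer(emission_years)),
            class = "world_config")
}

# low-order harmonic surface on a grid, scaled into [lo, hi]
harmonic_surface <- function(grid, k_lat, k_lon, phase, lo, hi) {
  lat <- grid$lat; lon <- grid$lon_norm
  s <- outer(sinpi(k_lat * (lat + 90) / 180 + phase),
             cospi(k_lon * (lon + 180) / 180 - phase), `+`)
  lo + (hi - lo) * (s - min(s)) / max(max(s) - min(s), .Machine$double.eps)
}

block_country_codes <- function(nlat, nlon, n_countries) {
  # contiguous lat/lon blocks over a central "continent", ocean elsewhere
  codes <- matrix(NA_character_, nlat, nlon)
  li <- seq(max(1L, round(nlat * 0.2)), min(nlat, round(nlat * 0.85)))
  lj <- seq(max(1L, round(nlon * 0.1)), min(nlon, round(nlon * 0.9)))
  n_rows <- max(1L, floor(sqrt(n_countries)))
  n_cols <- ceiling(n_countries / n_rows)
  chunk <- function(n, k) rep(seq_len(k), each = ceiling(n / k), length.out = n)
  row_of <- chunk(length(li), n_rows)
  col_of <- chunk(length(lj), n_cols)
  iso <- sprintf("C%02d", seq_len(n_countries))
  for (a in seq_along(li)) for (b in seq_along(lj)) {
    k <- (row_of[a] - 1L) * n_cols + col_of[b]
    if (k <= n_countries) codes[li[a], lj[b]] <- iso[k]
  }
  codes
}

#' Generate a synthetic world with known ground truth
#'
#' Builds, deterministically from the seed: a smooth deposition field with a
#' linear temporal trend per cell, exactly affine in a co-generated emission
#' field (`dep = a + b * emis`, plus optional Gaussian noise `sigma`); five
#' crop-type fraction fields on the nested finer grid; a block-country mask;
#' decadal HYDE-style cropland area sources; daily station records whose
#' annualized flux hits a chosen target exactly; and budget tables with
#' known NUE. The ground-truth national table is computed at generation
#' time by a direct per-cell loop, independent of the pipeline functions.
#'
#' @param config a [world_config()].
#' @param seed integer seed; the same seed reproduces the world bitwise.
#' @return A list of class `synthetic_world`; see Details in the package
#'   vignette. Key elements: `deposition` (truth, all years incl. 1960),
#'   `emission`, `cropland_fractions`, `hyde_sources`, `mask`,
#'   `truth_rate`, `truth_total`, `stations`, `budget`, `nue_target`.
#' @export
generate_world <- function(config = world_config(), seed = 1L) {
  stopifnot(inherits(config, "world_config"))
  nlat <- config$nlat; nlon <- config$nlon; refine <- config$refine
  grid <- grid_spec(seq(-90 + 90 / nlat, 90 - 90 / nlat, length.out = nlat),
                    seq(-180 + 180 / nlon, 180 - 180 / nlon, length.out = nlon))
  fstep_lat <- grid$lat_step / refine; fstep_lon <- grid$lon_step / refine
  fine <- grid_spec(
    seq(min(grid$lat) - grid$lat_step / 2 + fstep_lat / 2,
        max(grid$lat) + grid$lat_step / 2 - fstep_lat / 2, by = fstep_lat),
    seq(min(grid$lon) - grid$lon_step / 2 + fstep_lon / 2,
        max(grid$lon) + grid$lon_step / 2 - fstep_lon / 2, by = fstep_lon))

  # per-cell affine relation dep = a + b * emis, smooth in space
  set.seed(sub_seed(seed, 1L))
  a <- harmonic_surface(grid, 2, 3, stats::runif(1), 1, 4)
  b <- harmonic_surface(grid, 3, 2, stats::runif(1), 0.3, 0.9)
  # emission: positive, smooth, linear temporal ramp per cell
  set.seed(sub_seed(seed, 2L))
  e0 <- harmonic_surface(grid, 1, 2, stats::runif(1), 5, 15)
  e1 <- harmonic_surface(grid, 2, 1, stats::runif(1), 0.02, 0.10)
  emis_at <- function(y) e0 + e1 * (y - 1970)
  all_years <- sort(unique(c(1960L, config$years)))
  dep_truth <- vector("list", length(all_years)); names(dep_truth) <- all_years
  set.seed(sub_seed(seed, 6L))
  hold_from <- 2018L
  for (y in all_years) {
    ye <- min(y, hold_from)           # deposition held after hold_from
    v <- a + b * emis_at(ye)
    if (config$sigma > 0)
      v <- pmax(v + stats::rnorm(length(v), 0, config$sigma), 0)
    dep_truth[[as.character(y)]] <-
      annual_field(grid, v, "kg N ha-1 yr-1", y)
  }
  emission <- stats::setNames(lapply(config$emission_years, function(y)
    annual_field(grid, emis_at(y), "kg N", y)), config$emission_years)

  # five crop-type fractions on the fine grid; constant in time
  set.seed(sub_seed(seed, 3L))
  fr <- lapply(1:5, function(k)
    annual_field(fine,
                 harmonic_surface(fine, k, 6 - k, stats::runif(1), 0, 0.18),
                 "fraction", year = 2015L))
  stack <- vapply(fr, function(f) f$values, fr[[1]]$values)
  frac_max <- apply(stack, c(1, 2), max)            # LUH2-style dominant type
  frac_sum <- pmin(apply(stack, c(1, 2), sum), 1)   # HYDE-style total cropland

  # independent fine-cell spherical areas and nested-block aggregation
  R <- 6371
  f_top <- fine$lat + fine$lat_step / 2; f_bot <- fine$lat - fine$lat_step / 2
  fine_area <- matrix(R^2 * (fine$lon_step * pi / 180) *
                        (sinpi(f_top / 180) - sinpi(f_bot / 180)) * 100,
                      length(fine$lat), length(fine$lon))
  crop_fine <- frac_max * fine_area
  crop_fine_hyde <- frac_sum * fine_area
  crop_coarse <- crop_coarse_hyde <- matrix(0, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    ii <- ((i - 1L) * refine + 1L):(i * refine)
    jj <- ((j - 1L) * refine + 1L):(j * refine)
    crop_coarse[i, j] <- sum(crop_fine[ii, jj])
    crop_coarse_hyde[i, j] <- sum(crop_fine_hyde[ii, jj])
  }

  codes <- block_country_codes(nlat, nlon, config$n_countries)
  mask <- rasterize_countries(codes, grid)

  # HYDE-style decadal area sources on the fine grid (constant cropland)
  hyde_years <- sort(unique(hyde_year_map(config$years)))
  hyde_sources <- stats::setNames(lapply(hyde_years, function(y)
    annual_field(fine, crop_fine_hyde, "ha", y)), hyde_years)

  # ground-truth national tables: direct triple loop (cell x country),
  # bypassing national_rate/regrid_sum, for both cropland weightings
  iso <- mask$countries
  yrs_chr <- as.character(config$years)
  mk_tab <- function() matrix(NaN, length(iso), length(yrs_chr),
                              dimnames = list(iso, yrs_chr))
  truth_rate <- mk_tab(); truth_rate_hyde <- mk_tab()
  truth_total <- mk_tab(); truth_total[] <- 0
  area_c <- area_c_hyde <- stats::setNames(numeric(length(iso)), iso)
  for (k in seq_along(iso)) {
    sel <- !is.na(codes) & codes == iso[k]
    den <- den_h <- 0
    for (i in seq_len(nlat)) for (j in seq_len(nlon)) if (sel[i, j]) {
      den <- den + crop_coarse[i, j]
      den_h <- den_h + crop_coarse_hyde[i, j]
    }
    area_c[k] <- den; area_c_hyde[k] <- den_h
    for (yc in yrs_chr) {
      num <- num_h <- 0
      dv <- dep_truth[[yc]]$values
      for (i in seq_len(nlat)) for (j in seq_len(nlon)) if (sel[i, j]) {
        num <- num + dv[i, j] * crop_coarse[i, j]
        num_h <- num_h + dv[i, j] * crop_coarse_hyde[i, j]
      }
      if (den > 0) {
        truth_rate[iso[k], yc] <- num / den
        truth_total[iso[k], yc] <- num * 1e-9
      }
      if (den_h > 0) truth_rate_hyde[iso[k], yc] <- num_h / den_h
    }
  }

  # stations: daily records in country C01 whose annual flux hits targets
  set.seed(sub_seed(seed, 4L))
  st_years <- intersect(c(2000L, 2005L, 2010L), config$years)
  st_factor <- c(0.8, 0.95, 1.05, 1.2)
  st_lat <- grid$lat[min(5L, nlat)]; st_lon <- grid$lon[min(8L, nlon)]
  st_rows <- list()
  for (s in seq_along(st_factor)) for (y in st_years) {
    target <- truth_rate[1, as.character(y)] * st_factor[s]
    if (!is.finite(target)) next
    n_days <- 40L
    precip <- stats::runif(n_days, 2, 20)
    conc <- (target / 365) / (precip * 0.01)   # every day's flux = target/365
    dates <- as.Date(sprintf("%d-01-01", y)) +
      sort(sample.int(360L, n_days)) - 1L
    st_rows[[length(st_rows) + 1L]] <- data.frame(
      station_id = sprintf("ST%02d", s), lat = st_lat, lon = st_lon,
      date = dates, total_n_mg_per_l = conc, precip_mm = precip,
      stringsAsFactors = FALSE)
  }
  stations <- if (length(st_rows)) do.call(rbind, st_rows) else NULL
  if (!is.null(stations))
    stations$year <- as.integer(format(stations$date, "%Y"))
  station_targets <- if (length(st_years))
    do.call(rbind, lapply(st_years, function(y)
      data.frame(year = y,
                 targets = truth_rate[1, as.character(y)] * st_factor)))
    else NULL

  # budget tables with a known, slowly improving NUE target per year
  set.seed(sub_seed(seed, 5L))
  span <- max(1L, diff(range(config$years)))
  nue_target <- stats::setNames(
    0.45 + 0.20 * (config$years - min(config$years)) / span, config$years)
  bud <- expand.grid(country = iso, year = config$years,
                     stringsAsFactors = FALSE)
  bud <- bud[order(bud$country, bud$year), ]
  base_in <- stats::runif(length(iso), 5e7, 5e8)[match(bud$country, iso)]
  bud$n_sf <- base_in * 0.6
  bud$n_mn <- base_in * 0.3
  bud$n_bnf <- base_in * 0.1
  ad_wl <- truth_total[cbind(match(bud$country, iso),
                             match(bud$year, config$years))] * 1e9  # kg N
  bud$n_ad_wl <- ad_wl
  bud$n_ad_wh <- ad_wl * 1.05
  bud$n_ad_ah <- ad_wl * 0.90
  bud$n_ad_al <- ad_wl * 0.95
  bud$n_cr <- nue_target[as.character(bud$year)] *
    (bud$n_sf + bud$n_mn + bud$n_bnf + bud$n_ad_wl)

  structure(list(config = config, seed = as.integer(seed),
                 grid = grid, fine_grid = fine,
                 deposition = dep_truth, emission = emission,
                 cropland_fractions = fr, hyde_sources = hyde_sources,
                 mask = mask, codes = codes,
                 affine = list(a = a, b = b),
                 truth_rate = truth_rate, truth_rate_hyde = truth_rate_hyde,
                 truth_total = truth_total,
                 national_area = area_c, national_area_hyde = area_c_hyde,
                 stations = stations, station_targets = station_targets,
                 budget = bud, nue_target = nue_target),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world: %s coarse / %s fine, %d countries, years %d-%d, sigma=%g, seed=%d\n",
    format(x$grid), format(x$fine_grid), length(x$mask$countries),
    min(x$config$years), max(x$config$years), x$config$sigma, x$seed))
  invisible(x)
}

#' Restrict a deposition series to an anchor-availability pattern
#'
#' Drops all years not in the pattern; retained years are the untouched
#' truth fields. The withheld years form the recovery test set.
#'
#' @param series year-named list of deposition [annual_field()]s.
#' @param pattern integer years to retain (must be a subset of the series).
#' @return Year-named list containing only the pattern years.
#' @export
degrade_to_anchors <- function(series, pattern) {
  pattern <- as.integer(pattern)
  if (length(pattern) == 0L) stop("anchor pattern is empty")
  have <- as.integer(names(series))
  miss <- setdiff(pattern, have)
  if (length(miss)) stop("pattern year(s) not in series: ",
                         paste(miss, collapse = ", "))
  series[as.character(sort(intersect(pattern, have)))]
}
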
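# Adapters turning HYDE-style and LUH2-style cropland inputs into annual
# cropland-area fields (ha) on the deposition grid for 1961-2020.

#' HYDE-style source-year mapping
#'
#' HYDE-like reconstructions provide decadal maps from 1960 to 2000 and
#' annual maps 2001-2017. Each target year 1961-2020 maps onto the source
#' map actually used: 1961-1965 -> 1960, 1966-1975 -> 1970,
#' 1976-1985 -> 1980, 1986-1995 -> 1990, 1996-2000 -> 2000,
#' 2001-2017 -> the year itself, 2018-2020 -> 2017.
#'
#' @param year integer vector in 1961..2020.
#' @return integer vector of source years.
#' @examples
#' hyde_year_map(c(1973, 2005, 2019))  # 1970 2005 2017
#' @export
hyde_year_map <- function(year) {
  year <- as.integer(year)
  if (any(is.na(year)) || any(year < 1961L | year > 2020L))
    stop("year must lie in 1961..2020")
  out <- year
  out[year >= 1961L & year <= 1965L] <- 1960L
  out[year >= 1966L & year <= 1975L] <- 1970L
  out[year >= 1976L & year <= 1985L] <- 1980L
  out[year >= 1986L & year <= 1995L] <- 1990L
  out[year >= 1996L & year <= 2000L] <- 2000L
  out[year >= 2018L & year <= 2020L] <- 2017L
  out
}

#' LUH2-style hold rule for years past the last available map
#'
#' Identity up to `last_available` (annual maps exist); later years reuse
#' the `last_available` map.
#'
#' @param year integer vector in 1961..2020.
#' @param last_available last year with its own map (default 2015).
#' @return integer vector of source years.
#' @examples
#' luh2_year_hold(c(2010, 2018, 2020))  # 2010 2015 2015
#' @export
luh2_year_hold <- function(year, last_available = 2015L) {
  year <- as.integer(year)
  if (any(is.na(year)) || any(year < 1961L | year > 2020L))
    stop("year must lie in 1961..2020")
  pmin(year, as.integer(last_available))
}

#' Cropland area from LUH2-style crop functional-type fractions
#'
#' Of the five crop sub-type fractions (C3 annual, C3 perennial, C4 annual,
#' C4 perennial, C3 nitrogen-fixing), the per-cell maximum represents
#' cropland; the fraction is converted to area with the spherical cell area
#' and, if a coarser deposition grid is given, summed conservatively onto it.
#' `combine = "sum"` instead adds the five fractions (capped at 1) for
#' mixed-crop cells.
#'
#' @param fractions list of five [annual_field()]s with units `"fraction"`,
#'   co-registered on one grid.
#' @param dep_grid optional coarser [grid_spec()] to aggregate onto.
#' @param combine `"max"` (default) or `"sum"`.
#' @return An [annual_field()] with units `"ha"`.
#' @export
luh2_cropland_area <- function(fractions, dep_grid = NULL,
                               combine = c("max", "sum")) {
  combine <- match.arg(combine)
  if (length(fractions) != 5L)
    stop("expected five crop sub-type fraction fields, got ", length(fractions))
  g <- fractions[[1]]$grid
  for (f in fractions) {
    stopifnot(inherits(f, "annual_field"))
    if (f$units != "fraction") stop("all inputs must be fraction fields")
    if (!grids_identical(f$grid, g)) stop("fraction fields are not co-registered")
    fin <- f$values[is.finite(f$values)]
    if (length(fin) && (min(fin) < -1e-12 || max(fin) > 1 + 1e-12))
      stop("fraction outside [0, 1]")
  }
  stack <- vapply(fractions, function(f) f$values, fractions[[1]]$values)
  frac <- if (combine == "max") apply(stack, c(1, 2), max)
          else pmin(apply(stack, c(1, 2), sum), 1)
  area <- annual_field(g, frac * cell_areas(g)$values, units = "ha",
                       year = fractions[[1]]$year)
  if (!is.null(dep_grid) && !grids_identical(dep_grid, g))
    area <- regrid_sum(area, dep_grid)
  area
}

#' Build an annual cropland-area series 1961-2020
#'
#' Applies the source's year rule (HYDE-style piecewise-decadal map or
#' LUH2-style hold past the last available year) to produce a gap-free
#' series of cropland-area fields on the deposition grid. HYDE-like inputs
#' may be areas (ha) or land fractions; fractions are converted with the
#' spherical cell area.
#'
#' @param source_fields named list of [annual_field()]s, names = the source
#'   years available (e.g. `"1960"`, `"1970"`, ...). For `source = "luh2"`,
#'   each element is itself a list of five fraction fields.
#' @param source `"hyde"` or `"luh2"`.
#' @param dep_grid [grid_spec()] of the deposition grid.
#' @param years target years (default 1961:2020).
#' @param last_available for `"luh2"`, last year with a map (default 2015).
#' @param combine LUH2 fraction combination rule, see [luh2_cropland_area()].
#' @return An object of class `cropland_series`: list with `fields`
#'   (year-named list of ha fields), `source_year` (named integer vector),
#'   `provenance` tag.
#' @export
cropland_series <- function(source_fields, source = c("hyde", "luh2"),
                            dep_grid, years = 1961:2020,
                            last_available = 2015L,
                            combine = c("max", "sum")) {
  source <- match.arg(source)
  combine <- match.arg(combine)
  src_year <- if (source == "hyde") hyde_year_map(years)
              else luh2_year_hold(years, last_available)
  need <- sort(unique(src_year))
  have <- as.integer(names(source_fields))
  missing_years <- setdiff(need, have)
  if (length(missing_years))
    stop("missing source cropland map(s) for year(s): ",
         paste(missing_years, collapse = ", "))
  # convert each needed source map to ha on the deposition grid, once
  as_area <- function(x) {
    if (source == "luh2")
      return(luh2_cropland_area(x, dep_grid, combine = combine))
    stopifnot(inherits(x, "annual_field"))
    a <- if (x$units == "fraction")
      annual_field(x$grid, x$values * cell_areas(x$grid)$values,
                   units = "ha", year = x$year)
    else if (x$units == "ha") x
    else stop("HYDE-like input must be 'ha' or 'fraction', got '", x$units, "'")
    if (!grids_identical(a$grid, dep_grid)) a <- regrid_sum(a, dep_grid)
    a
  }
  converted <- lapply(source_fields[as.character(need)], as_area)
  fields <- stats::setNames(converted[as.character(src_year)],
                            as.character(years))
  for (i in seq_along(years)) fields[[i]]$year <- years[i]
  structure(list(fields = fields,
                 source_year = stats::setNames(src_year, years),
                 provenance = paste0(source, "-like")),
            class = "cropland_series")
}

#' @export
print.cropland_series <- function(x, ...) {
  yrs <- as.integer(names(x$fields))
  cat(sprintf("cropland_series (%s): years %d-%d, %d distinct source maps\n",
              x$provenance, min(yrs), max(yrs),
              length(unique(x$source_year))))
  invisible(x)
}
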
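# Cropland-area-weighted aggregation of gridded deposition to national
# rates (kg N ha-1 yr-1) and totals (Tg N yr-1).

#' Cropland-area-weighted national deposition rate
#'
#' For each country c, `rate_c = sum_i dep_i * w_i / sum_i w_i` with
#' `w_i = cropland_i * share_ic`, i.e. the mean deposition over the
#' country's cells weighted by the cropland area each cell contributes to
#' the country. Countries with zero cropland weight get `NaN`.
#'
#' @param dep deposition [annual_field()] (`"kg N ha-1 yr-1"`).
#' @param cropland cropland-area [annual_field()] (`"ha"`), same grid.
#' @param mask a [country_mask()] on the same grid.
#' @return Named numeric vector, one rate per country.
#' @export
national_rate <- function(dep, cropland, mask) {
  stopifnot(inherits(dep, "annual_field"), inherits(cropland, "annual_field"),
            inherits(mask, "country_mask"))
  if (!grids_identical(dep$grid, cropland$grid) ||
      !grids_identical(dep$grid, mask$grid))
    stop("deposition, cropland and mask grids do not match")
  if (cropland$units != "ha") stop("cropland must be an area field (ha)")
  d <- dep$values; a <- cropland$values
  d_ok <- is.finite(d); a[!is.finite(a)] <- 0
  out <- vapply(seq_along(mask$countries), function(k) {
    w <- a * mask$shares[, , k]
    w[!d_ok] <- 0
    sw <- sum(w)
    if (sw <= 0) return(NaN)
    sum(d[d_ok] * w[d_ok]) / sw
  }, numeric(1))
  stats::setNames(out, mask$countries)
}

#' National cropland area per country
#'
#' `area_c = sum_i cropland_i * share_ic` in ha.
#'
#' @inheritParams national_rate
#' @return Named numeric vector of areas (ha).
#' @export
national_cropland_area <- function(cropland, mask) {
  stopifnot(inherits(cropland, "annual_field"), inherits(mask, "country_mask"))
  if (!grids_identical(cropland$grid, mask$grid))
    stop("cropland and mask grids do not match")
  a <- cropland$values; a[!is.finite(a)] <- 0
  out <- vapply(seq_along(mask$countries),
                function(k) sum(a * mask$shares[, , k]), numeric(1))
  stats::setNames(out, mask$countries)
}

#' National deposition total from rate and cropland area
#'
#' `total_c = rate_c * area_c * 1e-9` converting kg N yr-1 to Tg N yr-1.
#' Countries with zero cropland get total 0 (default) or `NaN`.
#'
#' @param rate named rate vector from [national_rate()] (kg N ha-1 yr-1).
#' @param area named cropland-area vector (ha), same countries.
#' @param zero_area one of `"zero"` (default) or `"nan"`: value for
#'   countries with no cropland.
#' @return Named numeric vector of totals (Tg N yr-1).
#' @export
national_total <- function(rate, area, zero_area = c("zero", "nan")) {
  zero_area <- match.arg(zero_area)
  if (!identical(names(rate), names(area)))
    stop("rate and area country names do not match")
  if (any(area < 0, na.rm = TRUE)) stop("negative cropland area")
  tot <- rate * area * 1e-9
  empty <- !is.na(area) & area == 0
  tot[empty] <- if (zero_area == "zero") 0 else NaN
  tot
}

#' Build a country x year national table over a deposition series
#'
#' Applies [national_rate()] (and optionally [national_total()]) year by
#' year over a gap-filled deposition series and a cropland series.
#'
#' @param dep_series an `ndep_gapfill` object or a year-named list of
#'   deposition fields.
#' @param cropland a [cropland_series()] object or a year-named list of
#'   cropland-area fields.
#' @param mask a [country_mask()].
#' @param what `"rate"` (kg N ha-1 yr-1) or `"total"` (Tg N yr-1).
#' @return A `national_table`: numeric matrix countries x years with a
#'   `units` attribute; `NaN` marks country-years with no cropland.
#' @export
national_table <- function(dep_series, cropland, mask,
                           what = c("rate", "total")) {
  what <- match.arg(what)
  dep <- if (inherits(dep_series, "ndep_gapfill")) dep_series$series
         else dep_series
  crop <- if (inherits(cropland, "cropland_series")) cropland$fields
          else cropland
  years <- names(dep)
  miss <- setdiff(years, names(crop))
  if (length(miss)) stop("cropland series missing year(s): ",
                         paste(miss, collapse = ", "))
  tab <- matrix(NA_real_, length(mask$countries), length(years),
                dimnames = list(mask$countries, years))
  for (y in years) {
    r <- national_rate(dep[[y]], crop[[y]], mask)
    if (what == "total")
      r <- national_total(r, national_cropland_area(crop[[y]], mask))
    tab[, y] <- r
  }
  structure(tab, units = if (what == "rate") "kg N ha-1 yr-1" else "Tg N yr-1",
            class = c("national_table", "matrix", "array"))
}

#' @export
print.national_table <- function(x, ...) {
  cat(sprintf("national_table [%s]: %d countries x %d years\n",
              attr(x, "units"), nrow(x), ncol(x)))
  yrs <- colnames(x)
  show <- yrs[round(seq(1, length(yrs), length.out = min(6, length(yrs))))]
  print(round(unclass(x)[, show, drop = FALSE], 3))
  invisible(x)
}
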
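# Precipitation-chemistry station arithmetic: daily wet-deposition fluxes,
# annualization, and comparison of national products against station
# distributions.

#' Daily wet-deposition flux from concentration and precipitation
#'
#' `flux = concentration (mg N L-1) x precipitation (mm) x 0.01` in
#' kg N ha-1 day-1. The 0.01 factor is pure unit conversion: 1 mm of rain
#' on 1 ha is 1e4 L, so 1 mg L-1 deposits 1e4 mg = 0.01 kg per ha.
#'
#' @param conc total-N concentration in precipitation, mg N L-1 (>= 0).
#' @param precip daily precipitation depth, mm (>= 0). Recycled with `conc`.
#' @return Numeric vector of daily fluxes (kg N ha-1 day-1).
#' @examples
#' daily_flux(2, 10)  # 0.2
#' @export
daily_flux <- function(conc, precip) {
  if (any(conc < 0, na.rm = TRUE) || any(precip < 0, na.rm = TRUE))
    stop("concentration and precipitation must be non-negative")
  conc * precip * 0.01
}

#' Annualize daily wet-deposition fluxes
#'
#' `365 * mean(daily fluxes)` over the n days with data; 365 is used for
#' every year, leap years included. `NA` fluxes are dropped before the mean.
#'
#' @param fluxes daily fluxes (kg N ha-1 day-1) for one station-year.
#' @return Annual flux (kg N ha-1 yr-1); `NA` when no day has data.
#' @examples
#' annualize(rep(0.2, 100))  # 73
#' @export
annualize <- function(fluxes) {
  fluxes <- fluxes[!is.na(fluxes)]
  if (length(fluxes) == 0L) return(NA_real_)
  365 * mean(fluxes)
}

#' Read a station precipitation-chemistry CSV
#'
#' Expected columns: `station_id`, `lat`, `lon`, `date` (ISO 8601),
#' `total_n_mg_per_l`, `precip_mm`.
#'
#' @param path CSV file path.
#' @return A data.frame with the parsed columns plus `year`.
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lat", "lon", "date", "total_n_mg_per_l", "precip_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("station CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  df$year <- as.integer(format(df$date, "%Y"))
  df
}

#' Annual station fluxes from daily records
#'
#' Applies [daily_flux()] and [annualize()] per station and year.
#'
#' @param records data.frame as returned by [read_station_csv()].
#' @return data.frame with columns `station_id`, `year`,
#'   `flux_kg_ha_yr`, `n_days`.
#' @export
station_annual_flux <- function(records) {
  records$flux <- daily_flux(records$total_n_mg_per_l, records$precip_mm)
  ok <- !is.na(records$flux)
  agg <- stats::aggregate(flux ~ station_id + year, data = records[ok, ],
                          FUN = function(f) c(annualize(f), length(f)))
  out <- data.frame(station_id = agg$station_id, year = agg$year,
                    flux_kg_ha_yr = agg$flux[, 1], n_days = agg$flux[, 2],
                    stringsAsFactors = FALSE)
  out[order(out$station_id, out$year), , drop = FALSE]
}

# Linear-interpolation percentile between order statistics (the default
# quantile type 7): p-th percentile of sorted x at index 1 + p*(n-1).
interp_percentile <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = TRUE)
}

#' Compare a national product series against station distributions
#'
#' For each requested year, summarizes the distribution of station annual
#' fluxes (median, 25th/75th percentiles, min/max; percentiles by linear
#' interpolation between order statistics) and flags whether the national
#' product value falls within the interquartile range and within the full
#' station range. Years with no station data are omitted.
#'
#' @param product named numeric vector (names = years) of national
#'   deposition rates, or one row of a `national_table`.
#' @param station_annual data.frame from [station_annual_flux()].
#' @param years years to summarize (default: all years present in both).
#' @return data.frame with one row per year: `year`, `n_stations`,
#'   `st_min`, `st_q25`, `st_median`, `st_q75`, `st_max`, `product`,
#'   `within_iqr`, `within_range`.
#' @export
compare_to_stations <- function(product, station_annual, years = NULL) {
  pv <- as.numeric(product)
  names(pv) <- names(product)
  if (is.null(years))
    years <- intersect(as.integer(names(pv)), unique(station_annual$year))
  rows <- lapply(sort(years), function(y) {
    s <- station_annual$flux_kg_ha_yr[station_annual$year == y]
    s <- s[!is.na(s)]
    if (length(s) == 0L) return(NULL)
    p <- pv[[as.character(y)]]
    q <- interp_percentile(s, c(0.25, 0.5, 0.75))
    data.frame(year = y, n_stations = length(s),
               st_min = min(s), st_q25 = q[1], st_median = q[2],
               st_q75 = q[3], st_max = max(s), product = p,
               within_iqr = !is.na(p) && p >= q[1] && p <= q[3],
               within_range = !is.na(p) && p >= min(s) && p <= max(s))
  })
  do.call(rbind, rows)
}
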
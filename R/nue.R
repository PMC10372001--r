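# Nitrogen-use-efficiency sensitivity analysis: NUE per country-year and
# how it shifts when the deposition product is swapped.

#' Nitrogen use efficiency
#'
#' `NUE = N_CR / (N_SF + N_MN + N_BNF + N_AD)`: crop N removal over the sum
#' of inputs from synthetic fertilizer, manure, biological fixation and
#' atmospheric deposition. Dimensionless; not capped at 1 (soil mining can
#' push it above 1). `NaN` when the denominator is zero.
#'
#' @param cr,sf,mn,bnf,ad non-negative numeric vectors (consistent N-mass
#'   units), recycled to a common length.
#' @return Numeric vector of NUE values.
#' @examples
#' nue(50, 60, 20, 10, 10)  # 0.5
#' @export
nue <- function(cr, sf, mn, bnf, ad) {
  for (v in list(cr, sf, mn, bnf, ad))
    if (any(v < 0, na.rm = TRUE)) stop("budget components must be non-negative")
  denom <- sf + mn + bnf + ad
  out <- cr / denom
  out[!is.na(denom) & denom == 0] <- NaN
  out
}

#' NUE table for one deposition product
#'
#' Evaluates NUE for every row of a long budget table using the deposition
#' column of the chosen product.
#'
#' @param budget data.frame with columns `country`, `year`, `n_cr`, `n_sf`,
#'   `n_mn`, `n_bnf` and one `n_ad_<product>` column per product.
#' @param product product label, e.g. `"wl"`, `"ah"` (matched
#'   case-insensitively against the `n_ad_*` columns).
#' @return Numeric matrix country x year of NUE values.
#' @export
nue_table <- function(budget, product) {
  col <- paste0("n_ad_", tolower(product))
  if (!col %in% names(budget))
    stop("budget table has no column '", col, "'; available: ",
         paste(grep("^n_ad_", names(budget), value = TRUE), collapse = ", "))
  v <- nue(budget$n_cr, budget$n_sf, budget$n_mn, budget$n_bnf, budget[[col]])
  countries <- sort(unique(budget$country))
  years <- sort(unique(budget$year))
  tab <- matrix(NA_real_, length(countries), length(years),
                dimnames = list(countries, years))
  tab[cbind(match(budget$country, countries), match(budget$year, years))] <- v
  tab
}

#' Difference in NUE between a product and the reference
#'
#' `NUE_p - NUE_WL` elementwise over aligned country x year tables; `NaN`
#' propagates.
#'
#' @param nue_p,nue_ref country x year NUE matrices with identical dimnames.
#' @return Matrix of differences.
#' @export
nue_difference <- function(nue_p, nue_ref) {
  if (!identical(dimnames(nue_p), dimnames(nue_ref)))
    stop("NUE tables are not aligned (country/year dimnames differ)")
  nue_p - nue_ref
}

#' Per-country correlation of NUE between a product and the reference
#'
#' Pearson (default) correlation of the two NUE series across years,
#' country by country, with pairwise deletion of `NaN` years. Countries
#' with fewer than 3 paired years, or a constant series, get `NA` (with a
#' warning for the former).
#'
#' @param nue_p,nue_ref country x year NUE matrices with identical dimnames.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Named numeric vector of correlations per country.
#' @export
nue_correlation <- function(nue_p, nue_ref,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(dimnames(nue_p), dimnames(nue_ref)))
    stop("NUE tables are not aligned (country/year dimnames differ)")
  few <- character(0)
  out <- vapply(rownames(nue_p), function(cn) {
    x <- nue_p[cn, ]; y <- nue_ref[cn, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) { few <<- c(few, cn); return(NA_real_) }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok], method = method)
  }, numeric(1))
  if (length(few))
    warning("fewer than 3 paired years for: ", paste(few, collapse = ", "))
  out
}
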
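# Per-grid-cell gap filling of the 1961-2020 deposition series from anchor
# years: linear-in-year interpolation over the 1960s, deposition-on-emission
# regression elsewhere, and a hold rule for the final years.

#' Sum component deposition fields into bulk deposition
#'
#' Deposition supplied as separate reduced/oxidized x dry/wet components is
#' aggregated cellwise into a single bulk field.
#'
#' @param dry_nhy,wet_nhy,dry_nox,wet_nox co-registered [annual_field()]s,
#'   same year and units.
#' @return An [annual_field()], the cellwise sum.
#' @export
assemble_total <- function(dry_nhy, wet_nhy, dry_nox, wet_nox) {
  comps <- list(dry_nhy, wet_nhy, dry_nox, wet_nox)
  g <- comps[[1]]$grid
  for (f in comps) {
    stopifnot(inherits(f, "annual_field"))
    if (!grids_identical(f$grid, g)) stop("component grids do not match")
    if (f$units != comps[[1]]$units) stop("component units do not match")
  }
  annual_field(g, dry_nhy$values + wet_nhy$values + dry_nox$values +
                 wet_nox$values,
               units = comps[[1]]$units, year = comps[[1]]$year)
}

#' Linear-in-year interpolation between the 1960 and 1970 anchors
#'
#' Per cell, the straight line through (1960, d1960) and (1970, d1970)
#' evaluated at `year`.
#'
#' @param dep_1960,dep_1970 anchor [annual_field()]s on the same grid.
#' @param year integer strictly between 1960 and 1970.
#' @return An [annual_field()] for `year`.
#' @export
interp_eq1 <- function(dep_1960, dep_1970, year) {
  stopifnot(inherits(dep_1960, "annual_field"), inherits(dep_1970, "annual_field"))
  if (!grids_identical(dep_1960$grid, dep_1970$grid))
    stop("anchor grids do not match")
  year <- as.integer(year)
  if (year <= 1960L || year >= 1970L)
    stop("interp_eq1 interpolates years strictly between 1960 and 1970")
  slope <- (dep_1970$values - dep_1960$values) / 10
  annual_field(dep_1960$grid, dep_1960$values + slope * (year - 1960),
               units = dep_1960$units, year = year)
}

#' Fit the per-cell deposition-on-emission regression
#'
#' Ordinary least squares of deposition on emission, fitted independently in
#' every grid cell over the supplied anchor years. Cells with zero emission
#' variance (or any missing anchor value) are flagged degenerate; for those
#' the fallback prediction is the mean of the anchor-year deposition.
#'
#' @param dep_anchors named list (names = years) of deposition
#'   [annual_field()]s.
#' @param emis_anchors named list of emission [annual_field()]s covering the
#'   same years.
#' @return An object of class `eq2_params`: matrices `beta0`, `beta1`,
#'   logical `degenerate`, matrix `fallback` (anchor-mean deposition), and
#'   the anchor years.
#' @export
fit_eq2 <- function(dep_anchors, emis_anchors) {
  yrs <- intersect(names(dep_anchors), names(emis_anchors))
  if (length(yrs) < 2L)
    stop("need at least 2 common anchor years, got ", length(yrs))
  g <- dep_anchors[[yrs[1]]]$grid
  for (y in yrs) {
    if (!grids_identical(dep_anchors[[y]]$grid, g) ||
        !grids_identical(emis_anchors[[y]]$grid, g))
      stop("anchor grids do not match")
  }
  dims <- dim(dep_anchors[[yrs[1]]]$values)
  n <- length(yrs)
  D <- vapply(yrs, function(y) dep_anchors[[y]]$values, dep_anchors[[yrs[1]]]$values)
  E <- vapply(yrs, function(y) emis_anchors[[y]]$values, dep_anchors[[yrs[1]]]$values)
  dim(D) <- c(prod(dims), n); dim(E) <- c(prod(dims), n)
  ok <- rowSums(!is.finite(D)) == 0 & rowSums(!is.finite(E)) == 0
  mx <- rowMeans(E); my <- rowMeans(D)
  sxx <- rowSums((E - mx)^2)
  sxy <- rowSums((E - mx) * (D - my))
  degen <- !ok | sxx <= .Machine$double.eps * pmax(rowSums(E^2), 1)
  beta1 <- ifelse(degen, NA_real_, sxy / sxx)
  beta0 <- ifelse(degen, NA_real_, my - beta1 * mx)
  fallback <- rowMeans(D, na.rm = TRUE)
  fallback[!is.finite(fallback)] <- NA_real_
  shape <- function(v) { dim(v) <- dims; v }
  structure(list(grid = g, beta0 = shape(beta0), beta1 = shape(beta1),
                 degenerate = shape(degen), fallback = shape(fallback),
                 anchors = as.integer(yrs)),
            class = "eq2_params")
}

#' @export
print.eq2_params <- function(x, ...) {
  cat(sprintf(
    "eq2_params on %s: anchors {%s}, %d degenerate cell(s)\n",
    format(x$grid), paste(x$anchors, collapse = ", "), sum(x$degenerate)))
  invisible(x)
}

#' Predict deposition from emission with fitted regression parameters
#'
#' Per cell `max(0, beta0 + beta1 * emission)`; degenerate cells use the
#' anchor-mean fallback. Negative predictions are clipped at zero
#' (deposition is a non-negative flux) unless `clip_negative = FALSE`.
#'
#' @param params an `eq2_params` object from [fit_eq2()].
#' @param emission an emission [annual_field()] on the same grid.
#' @param clip_negative clip negative predictions at 0 (default `TRUE`).
#' @return An [annual_field()] with units `"kg N ha-1 yr-1"`; attribute
#'   `"n_clipped"` counts clipped cells.
#' @export
predict_eq2 <- function(params, emission, clip_negative = TRUE) {
  stopifnot(inherits(params, "eq2_params"), inherits(emission, "annual_field"))
  if (!grids_identical(params$grid, emission$grid))
    stop("emission grid does not match fitted grid")
  v <- params$beta0 + params$beta1 * emission$values
  v[params$degenerate] <- params$fallback[params$degenerate]
  n_clip <- 0L
  if (clip_negative) {
    neg <- is.finite(v) & v < 0
    n_clip <- sum(neg)
    v[neg] <- 0
  }
  out <- annual_field(params$grid, v, units = "kg N ha-1 yr-1",
                      year = emission$year)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Fill a 1961-2020 deposition series from anchor years and emissions
#'
#' The fitting function of the package: reconstructs a complete annual
#' deposition series from a partial set of anchor-year maps and annual
#' emission maps, per grid cell, in four regimes:
#' \enumerate{
#'   \item 1961-1969: linear in year through the 1960 and 1970 anchors
#'     ([interp_eq1()]).
#'   \item non-anchor years 1970-1996: deposition regressed on emission
#'     over the early anchors (default 1970, 1980, 1990, 1997), then
#'     predicted from the annual emission maps.
#'   \item 2014 up to `hold_from`: same regression refitted on the late
#'     anchors (default 1997-2013) and extrapolated.
#'   \item years after `hold_from` (default 2018): held at the `hold_from`
#'     value (no emission data).
#' }
#' Anchor years pass through unchanged. If the anchors already cover every
#' target year, gap filling is bypassed and the series is a passthrough.
#'
#' @param anchors named list (names = years, e.g. `"1960"`) of deposition
#'   [annual_field()]s, units `"kg N ha-1 yr-1"`.
#' @param emissions named list of emission [annual_field()]s (years
#'   1970-2018 for the default regimes).
#' @param years target years (default 1961:2020).
#' @param early_anchors,late_anchors anchor years for the two regression
#'   regimes.
#' @param hold_from last reconstructed year; later years copy it.
#' @param clip_negative clip negative predictions at 0.
#' @return An object of class `ndep_gapfill` with elements `series`
#'   (year-named list of fields), `provenance` (per-year regime:
#'   `observed-anchor`, `eq1-interp`, `eq2-interp`, `eq2-extrap`, `held`),
#'   `params_early`, `params_late`, `n_clipped` (per-year counts), `anchors`,
#'   `call`.
#' @examples
#' g <- grid_spec(c(0, 1), c(0, 1))
#' mk <- function(v, yr, u = "kg N ha-1 yr-1")
#'   annual_field(g, matrix(v, 2, 2), u, yr)
#' anchors <- c(
#'   list("1960" = mk(5, 1960)),
#'   stats::setNames(lapply(c(1970, 1980, 1990, 1997:2013),
#'     function(y) mk(5 + 0.1 * (y - 1960), y)),
#'     c(1970, 1980, 1990, 1997:2013)))
#' emis <- stats::setNames(lapply(1970:2018,
#'   function(y) mk(2 * (5 + 0.1 * (y - 1960)), y, "kg N")), 1970:2018)
#' fit <- ndep_gapfill(anchors, emis)
#' fit
#' @export
ndep_gapfill <- function(anchors, emissions, years = 1961:2020,
                         early_anchors = c(1970, 1980, 1990, 1997),
                         late_anchors = 1997:2013,
                         hold_from = 2018L, clip_negative = TRUE) {
  cl <- match.call()
  anchor_years <- as.integer(names(anchors))
  if (anyNA(anchor_years)) stop("anchors must be named by year")
  g <- anchors[[1]]$grid
  series <- vector("list", length(years)); names(series) <- years
  provenance <- stats::setNames(character(length(years)), years)
  n_clipped <- stats::setNames(integer(length(years)), years)

  if (all(years %in% anchor_years)) {
    # annual input: passthrough, no fitting
    for (y in years) {
      series[[as.character(y)]] <- anchors[[as.character(y)]]
      provenance[as.character(y)] <- "observed-anchor"
    }
    return(structure(list(series = series, provenance = provenance,
                          params_early = NULL, params_late = NULL,
                          n_clipped = n_clipped, anchors = anchor_years,
                          grid = g, years = years, call = cl),
                     class = "ndep_gapfill"))
  }

  need_eq1 <- any(years < 1970 & !(years %in% anchor_years))
  if (need_eq1) {
    for (y in c(1960L, 1970L))
      if (!y %in% anchor_years)
        stop("missing required anchor year ", y)
  }
  emis_years <- as.integer(names(emissions))
  pe <- pl <- NULL
  early_fill <- years[years >= 1970 & years <= 1996 & !(years %in% anchor_years)]
  late_fill <- years[years >= 2014 & years <= hold_from &
                       !(years %in% anchor_years)]
  chk_anchor <- function(req) {
    miss <- setdiff(req, anchor_years)
    if (length(miss)) stop("missing required anchor year ",
                           paste(miss, collapse = ", "))
  }
  if (length(early_fill)) {
    chk_anchor(early_anchors)
    miss_e <- setdiff(c(early_anchors, early_fill), emis_years)
    if (length(miss_e)) stop("missing emission map(s) for year(s): ",
                             paste(miss_e, collapse = ", "))
    pe <- fit_eq2(anchors[as.character(early_anchors)],
                  emissions[as.character(early_anchors)])
  }
  if (length(late_fill)) {
    chk_anchor(late_anchors)
    miss_e <- setdiff(c(late_anchors, late_fill), emis_years)
    if (length(miss_e)) stop("missing emission map(s) for year(s): ",
                             paste(miss_e, collapse = ", "))
    pl <- fit_eq2(anchors[as.character(late_anchors)],
                  emissions[as.character(late_anchors)])
  }

  for (y in years) {
    key <- as.character(y)
    if (y %in% anchor_years) {
      series[[key]] <- anchors[[key]]
      provenance[key] <- "observed-anchor"
    } else if (y < 1970) {
      series[[key]] <- interp_eq1(anchors[["1960"]], anchors[["1970"]], y)
      provenance[key] <- "eq1-interp"
    } else if (y <= 1996) {
      f <- predict_eq2(pe, emissions[[key]], clip_negative)
      n_clipped[key] <- attr(f, "n_clipped")
      series[[key]] <- f
      provenance[key] <- "eq2-interp"
    } else if (y <= hold_from) {
      f <- predict_eq2(pl, emissions[[key]], clip_negative)
      n_clipped[key] <- attr(f, "n_clipped")
      series[[key]] <- f
      provenance[key] <- "eq2-extrap"
    } else {
      held <- series[[as.character(hold_from)]]
      if (is.null(held)) stop("hold_from year ", hold_from,
                              " precedes the series; cannot hold")
      series[[key]] <- annual_field(held$grid, held$values, held$units, y)
      provenance[key] <- "held"
    }
  }
  structure(list(series = series, provenance = provenance,
                 params_early = pe, params_late = pl,
                 n_clipped = n_clipped, anchors = anchor_years,
                 grid = g, years = years, call = cl),
            class = "ndep_gapfill")
}

#' @export
print.ndep_gapfill <- function(x, ...) {
  cat("Gap-filled N-deposition series\n")
  cat("Call: "); print(x$call)
  tab <- table(factor(x$provenance,
                      levels = c("observed-anchor", "eq1-interp",
                                 "eq2-interp", "eq2-extrap", "held")))
  cat(sprintf("Years %d-%d on %s\n", min(x$years), max(x$years),
              format(x$grid)))
  for (nm in names(tab)) cat(sprintf("  %-16s %3d year(s)\n", nm, tab[[nm]]))
  if (sum(x$n_clipped) > 0)
    cat(sprintf("  %d negative prediction(s) clipped to 0\n", sum(x$n_clipped)))
  invisible(x)
}

#' @export
summary.ndep_gapfill <- function(object, ...) {
  gm <- vapply(object$series, function(f) mean(f$values, na.rm = TRUE),
               numeric(1))
  out <- list(call = object$call, provenance = object$provenance,
              grid_mean = gm, n_clipped = object$n_clipped,
              degenerate_early = if (!is.null(object$params_early))
                sum(object$params_early$degenerate) else NA_integer_,
              degenerate_late = if (!is.null(object$params_late))
                sum(object$params_late$degenerate) else NA_integer_)
  class(out) <- "summary.ndep_gapfill"
  out
}

#' @export
print.summary.ndep_gapfill <- function(x, ...) {
  cat("Gap-filled N-deposition series\n")
  cat("Call: "); print(x$call)
  cat("Grid-mean deposition (kg N ha-1 yr-1) by year:\n")
  print(round(stats::quantile(x$grid_mean), 4))
  cat(sprintf("Degenerate regression cells: early %s, late %s\n",
              x$degenerate_early, x$degenerate_late))
  cat(sprintf("Clipped negative predictions: %d\n", sum(x$n_clipped)))
  invisible(x)
}

#' Extract regression coefficients from a gap-fill fit
#'
#' @param object an `ndep_gapfill` object.
#' @param regime `"early"` or `"late"`.
#' @param ... unused.
#' @return List with per-cell `beta0` and `beta1` matrices, or `NULL` when
#'   the regime was not fitted.
#' @export
coef.ndep_gapfill <- function(object, regime = c("early", "late"), ...) {
  regime <- match.arg(regime)
  p <- if (regime == "early") object$params_early else object$params_late
  if (is.null(p)) return(NULL)
  list(beta0 = p$beta0, beta1 = p$beta1)
}

#' Predict deposition for new emission maps from a gap-fill fit
#'
#' @param object an `ndep_gapfill` object.
#' @param emission an emission [annual_field()], or omitted to return the
#'   fitted series.
#' @param regime which fitted regression to use.
#' @param ... unused.
#' @return An [annual_field()], or the full fitted series when `emission`
#'   is missing.
#' @export
predict.ndep_gapfill <- function(object, emission = NULL,
                                 regime = c("late", "early"), ...) {
  if (is.null(emission)) return(object$series)
  regime <- match.arg(regime)
  p <- if (regime == "early") object$params_early else object$params_late
  if (is.null(p)) stop("regime '", regime, "' was not fitted")
  predict_eq2(p, emission)
}

#' Anchor-year residuals of the emission regressions
#'
#' Observed anchor deposition minus the regression prediction at the same
#' year, per cell, for the requested regime.
#'
#' @param object an `ndep_gapfill` object.
#' @param regime `"early"` or `"late"`.
#' @param ... unused; `emissions` must be supplied via the stored call's
#'   environment, so residuals are available only when the regime was fitted.
#' @return Named list of residual matrices, one per anchor year, or `NULL`.
#' @export
residuals.ndep_gapfill <- function(object, regime = c("early", "late"), ...) {
  regime <- match.arg(regime)
  p <- if (regime == "early") object$params_early else object$params_late
  if (is.null(p)) return(NULL)
  anch <- as.character(p$anchors)
  # re-evaluate from the stored fitted series: anchor years are passthroughs
  env <- list(...)
  emis <- env$emissions
  if (is.null(emis)) stop("supply emissions = <named list of fields>")
  out <- lapply(anch, function(y) {
    obs <- object$series[[y]]$values
    pred <- p$beta0 + p$beta1 * emis[[y]]$values
    pred[p$degenerate] <- p$fallback[p$degenerate]
    obs - pred
  })
  stats::setNames(out, anch)
}

#' Plot the grid-mean reconstructed deposition series
#'
#' @param x an `ndep_gapfill` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ndep_gapfill <- function(x, ...) {
  gm <- vapply(x$series, function(f) mean(f$values, na.rm = TRUE), numeric(1))
  cols <- c(`observed-anchor` = "black", `eq1-interp` = "dodgerblue3",
            `eq2-interp` = "darkorange2", `eq2-extrap` = "firebrick3",
            held = "grey50")
  graphics::plot(x$years, gm, type = "l", col = "grey70",
                 xlab = "year", ylab = "grid-mean deposition (kg N ha-1 yr-1)",
                 ...)
  graphics::points(x$years, gm, pch = 19, col = cols[x$provenance])
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(x)
}
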
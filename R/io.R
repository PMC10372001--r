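# Plain-text readers and writers for gridded fields, country masks,
# national tables and budget tables. Gridded data travel as long-format CSV
# (year, lat, lon, value) with '#key=value' metadata header lines; values
# are printed with 17 significant digits so round trips are bitwise.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

read_meta <- function(path) {
  meta <- list()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  meta
}

#' Write gridded annual fields to long-format CSV
#'
#' @param fields a single [annual_field()] or a year-named list of them
#'   (one grid, one unit).
#' @param path output file.
#' @param variable variable name recorded in the metadata header.
#' @return `path`, invisibly.
#' @export
write_gridded <- function(fields, path, variable = "value") {
  if (inherits(fields, "annual_field")) fields <- list(fields)
  g <- fields[[1]]$grid
  rows <- lapply(fields, function(f) {
    stopifnot(inherits(f, "annual_field"))
    if (!grids_identical(f$grid, g)) stop("fields are not on one grid")
    data.frame(year = f$year,
               lat = rep(g$lat, times = length(g$lon)),
               lon = rep(g$lon, each = length(g$lat)),
               value = as.vector(f$values))
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("#variable=%s", variable),
               sprintf("#units=%s", fields[[1]]$units),
               "year,lat,lon,value"), con)
  writeLines(paste(df$year, fmt_num(df$lat), fmt_num(df$lon),
                   fmt_num(df$value), sep = ","), con)
  invisible(path)
}

#' Read gridded annual fields from long-format CSV
#'
#' Reconstructs the grid from the unique coordinates (latitude orientation
#' is normalized to ascending regardless of how the file is ordered) and
#' returns one [annual_field()] per year.
#'
#' @param path input file written by [write_gridded()] or following the
#'   same layout.
#' @param variable optional expected variable name; a mismatch is an error
#'   naming the variable the file holds.
#' @return Year-named list of [annual_field()]s (a single field is still
#'   wrapped in a list of length 1).
#' @export
read_gridded <- function(path, variable = NULL) {
  meta <- read_meta(path)
  if (!is.null(variable) && !is.null(meta$variable) &&
      !identical(meta$variable, variable))
    stop("variable '", variable, "' not found; file holds '",
         meta$variable, "'")
  units <- meta$units
  if (is.null(units)) stop("file has no '#units=' header: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("year", "lat", "lon", "value")
  if (!all(need %in% names(df)))
    stop("gridded CSV must have columns year, lat, lon, value")
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  g <- grid_spec(lat, lon)
  out <- lapply(split(df, df$year), function(d) {
    v <- matrix(NA_real_, length(lat), length(lon))
    v[cbind(match(d$lat, g$lat), match(d$lon, g$lon))] <- d$value
    annual_field(g, v, units, d$year[1])
  })
  out[order(as.integer(names(out)))]
}

#' Write a country mask to CSV
#'
#' Long format: `lat, lon, iso3, share`, zero shares omitted.
#'
#' @param mask a [country_mask()].
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  g <- mask$grid
  rows <- list()
  for (k in seq_along(mask$countries)) {
    s <- mask$shares[, , k]
    idx <- which(s > 0, arr.ind = TRUE)
    if (nrow(idx))
      rows[[k]] <- data.frame(lat = g$lat[idx[, 1]], lon = g$lon[idx[, 2]],
                              iso3 = mask$countries[k], share = s[idx])
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("#nlat=%d", length(g$lat)),
               sprintf("#nlon=%d", length(g$lon)),
               sprintf("#lat0=%.17g", g$lat[1]),
               sprintf("#lat_step=%.17g", g$lat_step),
               sprintf("#lon0=%.17g", g$lon[1]),
               sprintf("#lon_step=%.17g", g$lon_step),
               "lat,lon,iso3,share"), con)
  writeLines(paste(fmt_num(df$lat), fmt_num(df$lon), df$iso3,
                   fmt_num(df$share), sep = ","), con)
  invisible(path)
}

#' Read a country mask from CSV
#'
#' @param path file written by [write_mask()].
#' @return A [country_mask()].
#' @export
read_mask <- function(path) {
  meta <- read_meta(path)
  g <- grid_spec(as.numeric(meta$lat0) +
                   as.numeric(meta$lat_step) * (seq_len(as.integer(meta$nlat)) - 1),
                 as.numeric(meta$lon0) +
                   as.numeric(meta$lon_step) * (seq_len(as.integer(meta$nlon)) - 1))
  df <- utils::read.csv(path, comment.char = "#")
  iso <- sort(unique(df$iso3))
  shares <- array(0, dim = c(length(g$lat), length(g$lon), length(iso)),
                  dimnames = list(NULL, NULL, iso))
  shares[cbind(match(df$lat, g$lat), match(df$lon, g$lon),
               match(df$iso3, iso))] <- df$share
  country_mask(g, shares)
}

#' Write a national country x year table to CSV
#'
#' Rows are countries (ISO3 ascending), one column per year, `NaN` literal
#' for undefined country-years.
#'
#' @param table a `national_table` (or any countries x years matrix with
#'   dimnames).
#' @param path output file.
#' @export
write_national_table <- function(table, path) {
  tab <- unclass(table)
  tab <- tab[order(rownames(tab)), , drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  u <- attr(table, "units")
  if (!is.null(u)) writeLines(sprintf("#units=%s", u), con)
  writeLines(paste(c("country", colnames(tab)), collapse = ","), con)
  for (i in seq_len(nrow(tab))) {
    v <- sprintf("%.10g", tab[i, ])
    v[is.nan(tab[i, ])] <- "NaN"
    v[is.na(tab[i, ]) & !is.nan(tab[i, ])] <- "NaN"
    writeLines(paste(c(rownames(tab)[i], v), collapse = ","), con)
  }
  invisible(path)
}

#' Read a national table written by [write_national_table()]
#'
#' @param path CSV path.
#' @return Numeric matrix countries x years (class `national_table`).
#' @export
read_national_table <- function(path) {
  meta <- read_meta(path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  tab <- as.matrix(df[, -1, drop = FALSE])
  rownames(tab) <- df[[1]]
  structure(tab, units = meta$units,
            class = c("national_table", "matrix", "array"))
}

#' Write a synthetic world to a directory of plain-text inputs
#'
#' Emits the same formats the pipeline reads, so end-to-end runs go through
#' real I/O: annual truth deposition, anchor-pattern deposition, emissions,
#' five LUH2-style fraction fields and HYDE-style decadal area sources on
#' the fine grid, the country mask, station records, budget table, and a
#' flat key=value config.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gridded(world$deposition, p("deposition_annual.csv"), "ndep")
  anchors <- degrade_to_anchors(world$deposition, world$config$anchor_pattern)
  write_gridded(anchors, p("deposition_anchors.csv"), "ndep")
  write_gridded(world$emission, p("emission.csv"), "nemis")
  types <- c("c3ann", "c3per", "c4ann", "c4per", "c3nfx")
  for (k in 1:5)
    write_gridded(world$cropland_fractions[[k]],
                  p(sprintf("cropland_luh2_%s.csv", types[k])), types[k])
  write_gridded(world$hyde_sources, p("cropland_hyde.csv"), "cropland_ha")
  write_mask(world$mask, p("mask.csv"))
  if (!is.null(world$stations))
    utils::write.csv(world$stations, p("stations.csv"), row.names = FALSE)
  utils::write.csv(world$budget, p("budget.csv"), row.names = FALSE)
  writeLines(c(sprintf("seed=%d", world$seed),
               sprintf("sigma=%g", world$config$sigma),
               sprintf("years=%d:%d", min(world$config$years),
                       max(world$config$years)),
               sprintf("anchor_pattern=%s",
                       paste(world$config$anchor_pattern, collapse = " ")),
               "hold_from=2018"),
             p("world.cfg"))
  invisible(dir)
}

read_world_cfg <- function(dir) {
  lines <- readLines(file.path(dir, "world.cfg"))
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) x[2]),
                  vapply(kv, function(x) x[1], character(1)))
}

#' Build the four national deposition products from a world directory
#'
#' Reads the plain-text inputs written by [write_world()] (or prepared
#' externally in the same layout) and builds the four products: deposition
#' source A (annual maps, no gap filling) or W (anchor maps gap-filled with
#' the emission regression), crossed with cropland source H (HYDE-style
#' decadal areas) or L (LUH2-style max crop-type fraction). National rate
#' tables are written as `1_AH.csv`, `2_AL.csv`, `3_WH.csv`, `4_WL.csv`,
#' totals as `total_<P>.csv`.
#'
#' @param in_dir input directory.
#' @param out_dir output directory (created if needed).
#' @param verbose log per-year gap-fill provenance to stderr.
#' @return Named list of the four rate tables (`AH`, `AL`, `WH`, `WL`),
#'   invisibly; attribute `"gapfill"` holds the fitted `ndep_gapfill`.
#' @export
build_products <- function(in_dir, out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- read_world_cfg(in_dir)
  yr <- as.integer(strsplit(cfg$years, ":")[[1]])
  years <- yr[1]:yr[2]
  dep_annual <- read_gridded(file.path(in_dir, "deposition_annual.csv"))
  dep_anchor <- read_gridded(file.path(in_dir, "deposition_anchors.csv"))
  emission <- read_gridded(file.path(in_dir, "emission.csv"))
  mask <- read_mask(file.path(in_dir, "mask.csv"))
  grid <- mask$grid

  fit <- ndep_gapfill(dep_anchor, emission, years = years,
                      hold_from = as.integer(cfg$hold_from))
  if (verbose)
    message(paste(sprintf("year=%s regime=%s", names(fit$provenance),
                          fit$provenance), collapse = "\n"))

  types <- c("c3ann", "c3per", "c4ann", "c4per", "c3nfx")
  frac <- lapply(types, function(t)
    read_gridded(file.path(in_dir, sprintf("cropland_luh2_%s.csv", t)))[[1]])
  luh2_src <- list(frac)
  names(luh2_src) <- if (is.na(frac[[1]]$year)) "2015" else frac[[1]]$year
  # constant-in-time fraction maps cover every LUH2 source year
  need_l <- as.character(sort(unique(luh2_year_hold(years))))
  luh2_src <- stats::setNames(rep(luh2_src[1], length(need_l)), need_l)
  crop_l <- cropland_series(luh2_src, "luh2", grid, years)

  hyde_src <- read_gridded(file.path(in_dir, "cropland_hyde.csv"))
  crop_h <- cropland_series(hyde_src, "hyde", grid, years)

  dep_a <- dep_annual[as.character(years)]
  combos <- list(AH = list(dep_a, crop_h), AL = list(dep_a, crop_l),
                 WH = list(fit, crop_h), WL = list(fit, crop_l))
  files <- c(AH = "1_AH.csv", AL = "2_AL.csv", WH = "3_WH.csv", WL = "4_WL.csv")
  out <- list()
  for (nm in names(combos)) {
    rate <- national_table(combos[[nm]][[1]], combos[[nm]][[2]], mask, "rate")
    tot <- national_table(combos[[nm]][[1]], combos[[nm]][[2]], mask, "total")
    write_national_table(rate, file.path(out_dir, files[[nm]]))
    write_national_table(tot, file.path(out_dir, sprintf("total_%s.csv", nm)))
    out[[nm]] <- rate
  }
  attr(out, "gapfill") <- fit
  invisible(out)
}
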
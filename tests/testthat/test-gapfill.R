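test_that("component assembly is a cellwise sum that commutes with aggregation", {
  g <- grid_spec(c(0, 2), c(0, 2))
  comps <- lapply(1:4, function(v) mkfield(g, v, "kg N ha-1 yr-1", 2000))
  tot <- do.call(assemble_total, comps)
  expect_equal(tot$values, matrix(10, 2, 2))
  expect_equal(do.call(assemble_total,
                       lapply(1:4, function(v) mkfield(g, 0)))$values,
               matrix(0, 2, 2))
  # linearity: aggregate(sum of components) == sum(aggregate(component))
  set.seed(8)
  comps_r <- lapply(1:4, function(k)
    annual_field(g, matrix(runif(4, 0, 5), 2, 2), "kg N ha-1 yr-1", 2000))
  crop <- annual_field(g, matrix(runif(4, 10, 100), 2, 2), "ha")
  shares <- array(0, c(2, 2, 1), dimnames = list(NULL, NULL, "AAA"))
  shares[, , 1] <- 1
  mask <- country_mask(g, shares)
  r_sum <- national_rate(do.call(assemble_total, comps_r), crop, mask)
  r_parts <- Reduce(`+`, lapply(comps_r, function(f)
    national_rate(f, crop, mask)))
  expect_equal(unname(r_sum), unname(r_parts), tolerance = 1e-12)
  # grid mismatch
  g2 <- grid_spec(c(0, 2), c(1, 3))
  expect_error(assemble_total(comps[[1]], comps[[2]], comps[[3]],
                              mkfield(g2, 1)), "grids")
})

test_that("linear-in-year interpolation passes through the two anchors", {
  g <- grid_spec(c(0, 1), c(0, 1))
  d60 <- mkfield(g, 5, year = 1960); d70 <- mkfield(g, 15, year = 1970)
  expect_equal(interp_eq1(d60, d70, 1965)$values, matrix(10, 2, 2))
  expect_equal(interp_eq1(d60, d70, 1961)$values, matrix(6, 2, 2))
  const <- interp_eq1(mkfield(g, 7, year = 1960), mkfield(g, 7, year = 1970), 1964)
  expect_equal(const$values, matrix(7, 2, 2))
  expect_error(interp_eq1(d60, d70, 1970), "strictly between")
  expect_error(interp_eq1(d60, d70, 1950), "strictly between")
})

test_that("per-cell regression recovers exact affine relations", {
  g <- grid_spec(c(0, 1), c(0, 1))
  yrs <- c(1970, 1980, 1990, 1997)
  emis <- setNames(lapply(seq_along(yrs), function(i)
    mkfield(g, 4 + 2 * i, "kg N", yrs[i])), yrs)
  dep <- setNames(lapply(yrs, function(y)
    annual_field(g, 2 + 0.5 * emis[[as.character(y)]]$values,
                 "kg N ha-1 yr-1", y)), yrs)
  p <- fit_eq2(dep, emis)
  expect_equal(p$beta0, matrix(2, 2, 2), tolerance = 1e-12)
  expect_equal(p$beta1, matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_false(any(p$degenerate))
  # constant deposition, varying emission -> slope 0, intercept the constant
  dep_c <- setNames(lapply(yrs, function(y) mkfield(g, 7, year = y)), yrs)
  pc <- fit_eq2(dep_c, emis)
  expect_equal(pc$beta1, matrix(0, 2, 2), tolerance = 1e-12)
  expect_equal(pc$beta0, matrix(7, 2, 2), tolerance = 1e-12)
  expect_error(fit_eq2(dep[1], emis[1]), "at least 2")
})

test_that("noisy-anchor fits equal the normal-equations oracle to 1e-10", {
  set.seed(21)
  g <- grid_spec(seq(0, 8, 2), seq(0, 10, 2))
  yrs <- as.character(c(1970, 1980, 1990, 1997))
  emis_m <- lapply(yrs, function(y) matrix(runif(30, 1, 20), 5, 6))
  dep_m <- lapply(emis_m, function(e)
    2 + 0.4 * e + matrix(rnorm(30, 0, 0.5), 5, 6))
  emis <- setNames(Map(function(m, y) annual_field(g, m, "kg N", as.integer(y)),
                       emis_m, yrs), yrs)
  dep <- setNames(Map(function(m, y)
    annual_field(g, pmax(m, 0), "kg N ha-1 yr-1", as.integer(y)),
    dep_m, yrs), yrs)
  p <- fit_eq2(dep, emis)
  o <- oracle_ols(lapply(dep, function(f) f$values),
                  lapply(emis, function(f) f$values))
  expect_lt(max(abs(p$beta0 - o$beta0)), 1e-10)
  expect_lt(max(abs(p$beta1 - o$beta1)), 1e-10)
})

test_that("degenerate cells fall back to the anchor-mean deposition", {
  g <- grid_spec(c(0, 1), c(0, 1))
  yrs <- as.character(c(1997, 2000, 2005))
  # cell [1,1] has zero emission variance
  emis <- setNames(lapply(yrs, function(y) {
    v <- matrix(c(5, 1, 2, 3) + as.numeric(y) %% 7, 2, 2); v[1, 1] <- 5
    annual_field(g, v, "kg N", as.integer(y))
  }), yrs)
  dep <- setNames(lapply(seq_along(yrs), function(i)
    mkfield(g, c(4, 6, 8)[i], year = as.integer(yrs[i]))), yrs)
  p <- fit_eq2(dep, emis)
  expect_true(p$degenerate[1, 1])
  expect_false(p$degenerate[2, 2])
  pred <- predict_eq2(p, emis[[1]])
  expect_equal(pred$values[1, 1], 6)  # mean(4, 6, 8)
})

test_that("prediction clips negative values and counts clip events", {
  g <- grid_spec(c(0, 1), c(0, 1))
  yrs <- as.character(c(1997, 2005))
  emis <- setNames(lapply(c(2, 10), function(v)
    mkfield(g, v, "kg N")), yrs)
  dep <- setNames(lapply(c(9, 1), function(v) mkfield(g, v)), yrs)
  p <- fit_eq2(dep, emis)       # slope -1, intercept 11
  pred <- predict_eq2(p, mkfield(g, 20, "kg N"))
  expect_equal(pred$values, matrix(0, 2, 2))
  expect_equal(attr(pred, "n_clipped"), 4L)
  pred_raw <- predict_eq2(p, mkfield(g, 20, "kg N"), clip_negative = FALSE)
  expect_equal(pred_raw$values, matrix(-9, 2, 2))
  # direct evaluation: beta0=2, beta1=0.5, emission 8 -> 6
  p2 <- p; p2$beta0[] <- 2; p2$beta1[] <- 0.5; p2$degenerate[] <- FALSE
  expect_equal(predict_eq2(p2, mkfield(g, 8, "kg N"))$values[1, 1], 6)
})

test_that("the full series reconstructs an exactly affine world to 1e-9", {
  tw <- tiny_affine_world()
  fit <- ndep_gapfill(tw$anchors, tw$emissions)
  for (y in as.character(1961:2020)) {
    expect_lt(max(abs(fit$series[[y]]$values - tw$truth[[y]]$values)), 1e-9)
  }
  # anchor years are bit-identical passthroughs
  for (y in intersect(names(tw$anchors), as.character(1961:2020)))
    expect_identical(fit$series[[y]]$values, tw$anchors[[y]]$values)
  # regime labels
  expect_equal(unname(fit$provenance["1985"]), "eq2-interp")
  expect_equal(unname(fit$provenance["2016"]), "eq2-extrap")
  expect_equal(unname(fit$provenance["2020"]), "held")
  expect_equal(unname(fit$provenance["1965"]), "eq1-interp")
  expect_equal(unname(fit$provenance["2000"]), "observed-anchor")
  # never negative
  expect_true(all(vapply(fit$series, function(f)
    all(f$values >= 0), logical(1))))
})

test_that("constant anchors and emissions give a constant series", {
  g <- grid_spec(c(0, 1), c(0, 1))
  ay <- c(1960, 1970, 1980, 1990, 1997:2013)
  anchors <- setNames(lapply(ay, function(y) mkfield(g, 3, year = y)), ay)
  emis <- setNames(lapply(1970:2018, function(y)
    mkfield(g, 5, "kg N", y)), 1970:2018)
  fit <- ndep_gapfill(anchors, emis)
  for (f in fit$series) expect_equal(f$values, matrix(3, 2, 2))
})

test_that("missing required anchors are errors naming the year", {
  tw <- tiny_affine_world()
  expect_error(ndep_gapfill(tw$anchors[names(tw$anchors) != "1960"],
                            tw$emissions), "1960")
  expect_error(ndep_gapfill(tw$anchors[names(tw$anchors) != "1970"],
                            tw$emissions), "1970")
})

test_that("annual anchor coverage bypasses gap filling entirely", {
  tw <- tiny_affine_world()
  fit <- ndep_gapfill(tw$truth, tw$emissions)
  expect_true(all(fit$provenance == "observed-anchor"))
  expect_null(fit$params_early)
})

test_that("model methods expose coefficients, predictions and residuals", {
  tw <- tiny_affine_world()
  fit <- ndep_gapfill(tw$anchors, tw$emissions)
  co <- coef(fit, "early")
  expect_equal(co$beta0, tw$a, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(co$beta1, tw$b, tolerance = 1e-9, ignore_attr = TRUE)
  pr <- predict(fit, tw$emissions[["2010"]], regime = "late")
  expect_lt(max(abs(pr$values - tw$truth[["2010"]]$values)), 1e-9)
  res <- residuals(fit, "late", emissions = tw$emissions)
  expect_lt(max(abs(res[["2005"]])), 1e-9)
  expect_output(print(fit), "eq2-interp")
  s <- summary(fit)
  expect_s3_class(s, "summary.ndep_gapfill")
  expect_equal(s$degenerate_early, 0L)
})
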
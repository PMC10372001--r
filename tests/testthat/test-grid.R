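test_that("grid_spec validates spacing, pole limits and lon span", {
  expect_error(grid_spec(c(0, 1, 3), c(0, 1)), "not uniform")
  expect_error(grid_spec(c(89, 90), c(0, 1)), "past the poles")
  expect_error(grid_spec(c(0, 1), seq(0, 400, by = 10)), "exceeds 360")
  g <- grid_spec(c(10, 5, 0), c(350, 355))  # descending lat, lon > 180
  expect_equal(g$lat, c(0, 5, 10))           # normalized ascending
  expect_equal(g$lon_norm, c(-10, -5))       # normalized to [-180, 180)
})

test_that("annual_field enforces shape and unit-specific ranges", {
  g <- grid_spec(c(0, 1), c(0, 1, 2))
  expect_error(annual_field(g, matrix(0, 3, 2), "ha"), "shape")
  expect_error(annual_field(g, matrix(1.5, 2, 3), "fraction"), "outside")
  expect_error(annual_field(g, matrix(-1, 2, 3), "ha"), "negative")
  f <- annual_field(g, matrix(1:6, 2, 3), "kg N ha-1 yr-1", 2000)
  expect_s3_class(f, "annual_field")
  expect_identical(f$year, 2000L)
})

test_that("cell areas are symmetric about the equator and match the closed form", {
  g <- grid_spec(seq(-89.5, 89.5, by = 1), seq(-179.5, 179.5, by = 1))
  A <- cell_areas(g)$values
  # mirror symmetry
  expect_equal(A[1, ], A[nrow(A), ])
  expect_equal(A[30, 5], A[181 - 30, 250])
  # longitude independence
  expect_true(all(apply(A, 1, function(r) diff(range(r))) == 0))
  # global sum = sphere surface 4*pi*R^2
  sphere_ha <- 4 * pi * 6371^2 * 100
  expect_lt(abs(sum(A) - sphere_ha) / sphere_ha, 1e-4)
  # 1x1 degree cell centered on the equator: ~1.236e6 ha
  eq <- oracle_cell_area_ha(-0.5, 0.5, 0, 1)
  expect_equal(eq / 1e6, 1.236, tolerance = 1e-3)
  A_eq <- cell_areas(grid_spec(c(-1, 0, 1), c(0.5)))$values
  expect_equal(A_eq[2, 1], eq, tolerance = 1e-12)
  # per-cell closed-form agreement everywhere
  for (i in c(1, 45, 90, 180)) {
    o <- oracle_cell_area_ha(g$lat[i] - 0.5, g$lat[i] + 0.5, 0, 1)
    expect_equal(A[i, 1], o, tolerance = 1e-12)
  }
  expect_error(cell_areas(structure(list(lat = c(89, 91), lon = 0,
                                         lat_step = 2, lon_step = 1),
                                    class = "grid_spec")), "poles")
})

test_that("regrid_sum conserves mass on nested and non-nested grids", {
  set.seed(11)
  fine <- grid_spec(seq(-59.25, 59.25, by = 1.5), seq(-89.25, 89.25, by = 1.5))
  coarse_nested <- grid_spec(seq(-57, 57, by = 6), seq(-87, 87, by = 6))
  coarse_shifted <- grid_spec(seq(-58, 58, by = 5.8),
                              seq(-87.9, 87.9, length.out = 28))
  for (cg in list(coarse_nested, coarse_shifted)) {
    v <- matrix(runif(80 * 120, 0, 50), 80, 120)
    f <- annual_field(fine, v, "ha")
    out <- regrid_sum(f, cg)
    expect_lt(abs(sum(out$values) - sum(v)) / sum(v), 1e-9)
  }
})

test_that("regrid_sum refuses intensive (rate) fields", {
  fine <- grid_spec(c(0, 1), c(0, 1))
  coarse <- grid_spec(0.5, 0.5)
  f <- annual_field(fine, matrix(1, 2, 2), "kg N ha-1 yr-1")
  expect_error(regrid_sum(f, coarse), "extensive")
})

test_that("nested 2x2 block sums to the parent cell", {
  fine <- grid_spec(c(-0.5, 0.5), c(-0.5, 0.5))
  coarse <- grid_spec(0, 0, lat_step = 2, lon_step = 2)
  f <- annual_field(fine, matrix(c(1, 2, 3, 4), 2, 2), "ha")
  out <- regrid_sum(f, coarse)
  expect_equal(out$values[1, 1], 10)
})

test_that("a straddling fine cell splits 30/70 by fractional overlap", {
  # one fine cell [-0.5, 0.5] in lon; coarse boundary at lon = -0.2
  fine <- grid_spec(0, 0)
  coarse <- grid_spec(0, c(-1.45, 1.05))  # width 2.5, edges at -2.7,-0.2,2.3
  f <- annual_field(fine, matrix(10, 1, 1), "ha")
  out <- regrid_sum(f, coarse)
  # brute-force oracle: sample points uniformly in the fine cell
  xs <- seq(-0.5 + 1e-6, 0.5 - 1e-6, length.out = 200001)
  frac_left <- mean(xs < -0.2)
  expect_equal(out$values[1, 1], 10 * 0.3, tolerance = 1e-9)
  expect_equal(out$values[1, 2], 10 * 0.7, tolerance = 1e-9)
  expect_equal(frac_left, 0.3, tolerance = 1e-4)
})

test_that("missing fine cells count as zero unless all contributors are missing", {
  fine <- grid_spec(c(-0.5, 0.5), c(-0.5, 0.5, 1.5, 2.5))
  coarse <- grid_spec(0, c(0, 2), lat_step = 2)
  v <- matrix(c(1, 2, 3, 4, NA, NA, NA, NA), 2, 4)
  out <- regrid_sum(annual_field(fine, v, "ha"), coarse)
  expect_equal(out$values[1, 1], 10)       # partial NA -> treated as 0
  v2 <- v; v2[, 3:4] <- NA
  out2 <- regrid_sum(annual_field(fine, v2, "ha"), coarse)
  expect_true(is.na(out2$values[1, 2]))    # all-NA -> NA
})

test_that("country masks validate shares and rasterize code grids exactly", {
  g <- grid_spec(c(0, 1), c(0, 1))
  bad <- array(0.6, dim = c(2, 2, 2), dimnames = list(NULL, NULL, c("AAA", "BBB")))
  expect_error(country_mask(g, bad), "more than 1")
  codes <- matrix(c("AAA", "AAA", NA, "BBB"), 2, 2)
  m <- rasterize_countries(codes, g)
  expect_equal(sort(m$countries), c("AAA", "BBB"))
  expect_equal(unname(m$shares[1, 1, "AAA"]), 1)
  expect_equal(unname(m$shares[1, 2, "AAA"]), 0)
  expect_equal(sum(m$shares[1, 2, ]), 0)   # ocean cell
})

test_that("polygon rasterization recovers exact rectangle coverage", {
  g <- grid_spec(c(0.5, 1.5, 2.5), c(0.5, 1.5, 2.5))
  # rectangle exactly covering the lower-left 2x2 block of cells
  poly <- list(AAA = cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)))
  m <- rasterize_countries(poly, g)
  expect_equal(m$shares[1:2, 1:2, "AAA"], matrix(1, 2, 2))
  expect_equal(sum(m$shares[, , "AAA"]), 4)
  # half-cell coverage
  half <- list(BBB = cbind(c(0, 1, 1, 0), c(0, 0, 0.5, 0.5)))
  m2 <- rasterize_countries(half, g)
  expect_equal(unname(m2$shares[1, 1, "BBB"]), 0.5, tolerance = 1e-12)
})

test_that("random toy polygons give shares that match a Monte-Carlo oracle", {
  set.seed(31)
  g <- grid_spec(c(0.5, 1.5, 2.5), c(0.5, 1.5, 2.5))
  for (rep in 1:5) {
    # random triangle inside the grid
    tri <- cbind(runif(3, 0, 3), runif(3, 0, 3))
    m <- rasterize_countries(list(TTT = tri), g)
    expect_true(all(m$shares >= 0 & m$shares <= 1 + 1e-9))
    expect_lte(max(apply(m$shares, c(1, 2), sum)), 1 + 1e-9)
    # Monte-Carlo point-in-polygon for one covered cell
    idx <- which(m$shares[, , 1] > 0.05, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    i <- idx[1, 1]; j <- idx[1, 2]
    n <- 40000
    px <- runif(n, g$lon[j] - 0.5, g$lon[j] + 0.5)
    py <- runif(n, g$lat[i] - 0.5, g$lat[i] + 0.5)
    # ray-cast point-in-triangle via barycentric sign test
    sgn <- function(p1x, p1y, p2x, p2y, p3x, p3y)
      (p1x - p3x) * (p2y - p3y) - (p2x - p3x) * (p1y - p3y)
    d1 <- sgn(px, py, tri[1, 1], tri[1, 2], tri[2, 1], tri[2, 2])
    d2 <- sgn(px, py, tri[2, 1], tri[2, 2], tri[3, 1], tri[3, 2])
    d3 <- sgn(px, py, tri[3, 1], tri[3, 2], tri[1, 1], tri[1, 2])
    inside <- !((d1 < 0 | d2 < 0 | d3 < 0) & (d1 > 0 | d2 > 0 | d3 > 0))
    mc <- mean(inside)
    se <- sqrt(mc * (1 - mc) / n)
    expect_lt(abs(m$shares[i, j, 1] - mc), 5 * se + 1e-3)
  }
})

test_that("disjoint polygons have disjoint cell supports", {
  g <- grid_spec(seq(0.5, 5.5, 1), seq(0.5, 5.5, 1))
  polys <- list(AAA = cbind(c(0, 2.3, 2.3, 0), c(0, 0, 6, 6)),
                BBB = cbind(c(2.3, 6, 6, 2.3), c(0, 0, 6, 6)))
  m <- rasterize_countries(polys, g)
  tot <- apply(m$shares, c(1, 2), sum)
  expect_true(all(tot <= 1 + 1e-9))
  # the two supports only meet in boundary cells, where shares sum to <= 1
  both <- m$shares[, , "AAA"] > 1e-12 & m$shares[, , "BBB"] > 1e-12
  expect_true(all(abs(m$shares[, , "AAA"][both] +
                      m$shares[, , "BBB"][both] - 1) < 1e-9))
})
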
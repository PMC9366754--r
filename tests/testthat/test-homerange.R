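test_that("a single repeated point gives the bivariate Gaussian kernel", {
  pts <- data.frame(x = rep(0, 5), y = rep(0, 5))
  ud <- estimate_kde_ud(pts, bandwidth = 1, grid_resolution = 0.05, pad = 5)
  co <- raster_coords(ud)
  expected <- outer(co$y, co$x, function(y, x) dnorm(x) * dnorm(y))
  expect_equal(ud$values, expected / (sum(expected) * 0.05^2) * 1,
               tolerance = 1e-10)
  # and the grid mass is exactly one after normalization
  expect_equal(sum(ud$values) * ud$cell_size^2, 1, tolerance = 1e-9)
  # the raw (unnormalized) quadrature itself is near 1 on this fine grid
  expect_equal(sum(expected) * 0.05^2, 1, tolerance = 1e-4)
})

test_that("mirrored point sets give mirrored UDs", {
  set.seed(5)
  pts <- data.frame(x = rnorm(30), y = rnorm(30))
  ud1 <- estimate_kde_ud(pts, bandwidth = 0.5, grid_resolution = 0.1)
  ud2 <- estimate_kde_ud(transform(pts, x = -x), bandwidth = 0.5,
                         grid_resolution = 0.1)
  expect_equal(ud2$values[, ncol(ud2$values):1], ud1$values,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("UDs require at least 5 locations and positive bandwidth", {
  expect_error(estimate_kde_ud(data.frame(x = 1:4, y = 1:4)),
               "insufficient data")
  expect_error(estimate_kde_ud(data.frame(x = rep(1, 6), y = rep(1, 6))),
               "bandwidth")
})

test_that("isopleths enclose the requested UD mass and nest by level", {
  set.seed(9)
  pts <- data.frame(x = rnorm(60, sd = 2), y = rnorm(60, sd = 2))
  ud <- estimate_kde_ud(pts, bandwidth = 1, grid_resolution = 0.1)
  for (lv in c(0.5, 0.95, 0.99))
    expect_equal(attr(extract_isopleth(ud, lv), "mass"), lv,
                 tolerance = 0.005)
  a <- vapply(c(0.5, 0.95, 0.99), function(lv)
    extract_isopleth(ud, lv)$area, 0)
  expect_true(all(diff(a) > 0))
  expect_error(extract_isopleth(ud, 0), "level")
  expect_error(extract_isopleth(ud, 1.2), "level")
})

test_that("well-separated clusters give disjoint polygons with joint mass", {
  set.seed(11)
  pts <- data.frame(x = c(rnorm(40), rnorm(40, 30)), y = rnorm(80))
  ud <- estimate_kde_ud(pts, bandwidth = 1, grid_resolution = 0.15)
  hr <- extract_isopleth(ud, 0.99)
  expect_gte(length(hr$polygons), 2)
  expect_equal(attr(hr, "mass"), 0.99, tolerance = 0.005)
})

test_that("level = 1 returns the support of the density", {
  set.seed(3)
  pts <- data.frame(x = rnorm(20), y = rnorm(20))
  ud <- estimate_kde_ud(pts, bandwidth = 0.5, grid_resolution = 0.2)
  hr <- extract_isopleth(ud, 1)
  expect_equal(attr(hr, "mass"), 1, tolerance = 1e-9)
})

test_that("uniform polygon sampling is contained, reproducible and exact", {
  hr <- unit_square_hr()
  p1 <- sample_uniform_in_polygon(hr, 1000, seed = 42)
  p2 <- sample_uniform_in_polygon(hr, 1000, seed = 42)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 1000)
  expect_true(all(p1$x >= 0 & p1$x <= 1 & p1$y >= 0 & p1$y <= 1))
  expect_equal(nrow(sample_uniform_in_polygon(hr, 0)), 0)
  degenerate <- home_range(list(cbind(c(0, 1, 0), c(0, 0, 0))), area = 0)
  expect_error(sample_uniform_in_polygon(degenerate, 5), "degenerate")
})

test_that("sampling an L-shape hits sub-regions by area share", {
  # L: unit square minus its top-right quadrant -> area 0.75
  L <- home_range(list(cbind(c(0, 1, 1, 0.5, 0.5, 0),
                             c(0, 0, 0.5, 0.5, 1, 1))))
  expect_equal(L$area, 0.75)
  pts <- sample_uniform_in_polygon(L, 4000, seed = 7)
  frac <- mean(pts$x < 0.5 & pts$y < 0.5)   # area share 0.25/0.75
  se <- sqrt(1 / 3 * 2 / 3 / 4000)
  expect_lt(abs(frac - 1 / 3), 3 * se)
})

test_that("polygon sampling passes a chi-squared uniformity screen", {
  pts <- sample_uniform_in_polygon(unit_square_hr(), 10000, seed = 1)
  cell <- paste(findInterval(pts$x, c(0.25, 0.5, 0.75)),
                findInterval(pts$y, c(0.25, 0.5, 0.75)))
  counts <- table(factor(cell, levels = unique(cell)))
  stat <- sum((counts - 625)^2 / 625)
  expect_lt(stat, qchisq(0.99, df = 15))
})

test_that("a Gaussian UD's 99% isopleth is a circle of radius ~3.035 h", {
  pts <- data.frame(x = rep(0, 5), y = rep(0, 5))
  ud <- estimate_kde_ud(pts, bandwidth = 1, grid_resolution = 0.05, pad = 5)
  hr <- extract_isopleth(ud, 0.99)
  radii <- sqrt(rowSums(hr$polygons[[1]]^2))
  expect_equal(mean(radii), sqrt(qchisq(0.99, 2)), tolerance = 0.01)
  expect_lt(sd(radii), 0.01)
})

test_that("clipping restricts rings to the extent and preserves area", {
  hr <- unit_square_hr()
  clipped <- hr_clip(hr, c(xmin = 0.25, xmax = 2, ymin = -1, ymax = 0.75))
  expect_equal(clipped$area, 0.75 * 0.75)
  expect_true(all(hr_contains(clipped, c(0.5, 0.3), c(0.5, 0.5))))
  expect_false(any(hr_contains(clipped, c(0.1, 0.5), c(0.5, 0.9))))
  expect_error(hr_clip(hr, c(xmin = 5, xmax = 6, ymin = 5, ymax = 6)),
               "outside")
})

test_that("WKT export lists every ring", {
  hr <- home_range(list(cbind(c(0, 1, 1), c(0, 0, 1)),
                        cbind(c(5, 6, 6), c(5, 5, 6))))
  wkt <- hr_to_wkt(hr)
  expect_match(wkt, "^MULTIPOLYGON")
  expect_equal(lengths(regmatches(wkt, gregexpr("\\(\\(", wkt))), 2)
})
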
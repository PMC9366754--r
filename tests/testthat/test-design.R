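test_that("second-order tables have the design counts and containment", {
  st <- small_study()
  hrs <- lapply(1:3, function(i) {
    ci <- st$centres[i, ]
    th <- seq(0, 2 * pi, length.out = 60)
    home_range(list(cbind(ci$cx + 2000 * cos(th), ci$cy + 2000 * sin(th))),
               owner = ci$individual_id)
  })
  names(hrs) <- st$centres$individual_id[1:3]
  ext <- st$rasters$de
  pop <- home_range(list(cbind(
    c(2000, ext$n_cols * ext$cell_size - 2000,
      ext$n_cols * ext$cell_size - 2000, 2000),
    c(2000, 2000, ext$n_rows * ext$cell_size - 2000,
      ext$n_rows * ext$cell_size - 2000))), owner = "population")
  tab <- build_second_order_table(hrs, pop, st$rasters, n_used = 50,
                                  n_avail = 100, seed = 99)
  expect_equal(nrow(tab), 3 * 150)
  expect_equal(sum(tab$used), 3 * 50)
  expect_equal(unique(tab$weight[tab$used == 0]), 1000)
  expect_equal(unique(tab$weight[tab$used == 1]), 1)
  for (id in names(hrs)) {
    u <- tab[tab$used == 1 & tab$individual_id == id, ]
    expect_true(all(hr_contains(hrs[[id]], u$x, u$y)))
  }
  a <- tab[tab$used == 0, ]
  expect_true(all(hr_contains(pop, a$x, a$y)))
  tab2 <- build_second_order_table(hrs, pop, st$rasters, n_used = 50,
                                   n_avail = 100, seed = 99)
  expect_identical(tab, tab2)
})

test_that("third-order tables honour the availability ratio per individual", {
  st <- small_study()
  th <- seq(0, 2 * pi, length.out = 60)
  hrs <- lapply(1:2, function(i) {
    ci <- st$centres[i, ]
    home_range(list(cbind(ci$cx + 2200 * cos(th), ci$cy + 2200 * sin(th))))
  })
  names(hrs) <- st$centres$individual_id[1:2]
  used <- data.frame(
    animal_id = rep(names(hrs), c(10, 20)),
    x = c(st$centres$cx[1] + runif(10, -500, 500),
          st$centres$cx[2] + runif(20, -500, 500)),
    y = c(st$centres$cy[1] + runif(10, -500, 500),
          st$centres$cy[2] + runif(20, -500, 500)))
  tab <- build_third_order_table(used, hrs, st$rasters, ratio = 10,
                                 seed = 3)
  counts <- table(tab$individual_id, tab$used)
  expect_equal(unname(counts[, "1"]), c(10, 20))
  expect_equal(unname(counts[, "0"]), c(100, 200))
  # individuals with zero used rows are dropped with a warning
  hrs3 <- c(hrs, list(zz = hrs[[1]]))
  expect_warning(tab3 <- build_third_order_table(used, hrs3, st$rasters,
                                                 seed = 3),
                 "zero used")
  expect_false("zz" %in% tab3$individual_id)
  expect_identical(tab, build_third_order_table(used, hrs, st$rasters,
                                                ratio = 10, seed = 3))
})

test_that("standardization centres, scales, and inverts exactly", {
  tab <- data.frame(individual_id = "a", order = "third", used = 0:2 %% 2,
                    weight = 1, de = c(1, 2, 3), ml = c(4, 0, 2),
                    wf = c(0.5, 0.9, 0.6))
  std <- suppressWarnings(standardize_covariates(tab))
  expect_equal(std$de, c(-1, 0, 1))          # sample sd denominator = 1
  k <- attr(std, "standardization")
  expect_equal(unname(k$de), c(2, 1))
  for (cc in c("de", "ml", "wf")) {
    expect_equal(mean(std[[cc]]), 0, tolerance = 1e-10)
    expect_equal(sd(std[[cc]]), 1, tolerance = 1e-10)
  }
  back <- destandardize_covariates(std)
  expect_equal(back$de, tab$de, tolerance = 1e-12)
  expect_equal(back$ml, tab$ml, tolerance = 1e-12)
  # standardizing an already standardized column changes nothing
  std2 <- suppressWarnings(standardize_covariates(std))
  expect_equal(std2$de, std$de, tolerance = 1e-10)
})

test_that("degenerate and collinear covariates are flagged", {
  tab <- data.frame(individual_id = "a", order = "third", used = c(0, 1),
                    weight = 1, de = c(1, 1), ml = c(0, 1), wf = c(2, 5))
  expect_error(standardize_covariates(tab), "degenerate covariate")
  tab$de <- c(0, 2)   # de now perfectly collinear with ml
  expect_warning(std <- standardize_covariates(tab), "exceeds 0.50")
  expect_equal(abs(attr(std, "correlations")["de", "ml"]), 1)
})

test_that("the forage-risk squared correlation is exposed as a diagnostic", {
  st <- small_study()
  cc <- covariate_correlations(st$table)
  expect_equal(cc$r2["de", "ml"], cor(st$table$de, st$table$ml)^2)
  expect_true(cc$r2["de", "ml"] > 0.1)  # lion mixed onto forage by design
})

test_that("used-available tables round-trip losslessly through CSV", {
  st <- small_study()
  tab <- st$table[1:200, ]
  attr(tab, "standardization") <- attr(st$table, "standardization")
  attr(tab, "seed") <- 404
  path <- withr::local_tempfile(fileext = ".csv")
  write_ua_table(tab, path)
  back <- read_ua_table(path)
  expect_identical(back$de, tab$de)
  expect_identical(back$ml, tab$ml)
  expect_identical(back$weight, tab$weight)
  expect_equal(attr(back, "standardization"),
               attr(tab, "standardization"), tolerance = 1e-12)
  expect_equal(attr(back, "seed"), 404)
})
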
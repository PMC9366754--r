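test_that("landscape mixing controls the forage-risk correlation", {
  r0 <- generate_landscapes(n_rows = 96, n_cols = 96, mix_lion = 0,
                            seed = 5)
  r2_0 <- cor(as.vector(r0$de$values), log(as.vector(r0$lion$values)))^2
  expect_lt(r2_0, 0.05)
  r9 <- generate_landscapes(n_rows = 96, n_cols = 96, mix_lion = 0.95,
                            seed = 5)
  r2_9 <- cor(as.vector(r9$de$values), log(as.vector(r9$lion$values)))^2
  expect_gt(r2_9, 0.85)
  # forage stays in the stated kcal/g range, predators strictly positive
  expect_equal(range(r0$de$values), c(0.5, 3.0))
  expect_true(all(r0$lion$values > 0))
  expect_error(generate_landscapes(mix_lion = 1.2), "mix")
})

test_that("individual coefficient draws are hierarchically centred", {
  zero <- draw_individual_coefficients(
    8, sigma = c(de = 0, ml = 0, wf = 0, "de:ml" = 0, "de:wf" = 0),
    sigma_intercept = 0, seed = 3)
  expect_true(all(apply(zero, 2, sd) == 0))
  expect_equal(unname(zero[1, ]), c(0, 0.2, -0.1, 0.3, -0.1, 0.03))
  big <- draw_individual_coefficients(10000, seed = 4)
  se <- 0.15 / sqrt(10000)
  expect_lt(abs(mean(big[, "de"]) - 0.2), 3 * se)
  expect_equal(sd(big[, "de"]), 0.15, tolerance = 0.01)
  expect_identical(draw_individual_coefficients(10, seed = 9),
                   draw_individual_coefficients(10, seed = 9))
  expect_error(draw_individual_coefficients(5, sigma = c(de = -1, ml = 0,
                                                         wf = 0, "de:ml" = 0,
                                                         "de:wf" = 0)),
               "must be >= 0")
})

test_that("telemetry has the requested schedule and honours selection", {
  st <- small_study()
  g0 <- st$gamma[1:4, ]
  g0[] <- 0
  tel <- simulate_telemetry(st$rasters, g0, st$centres[1:4, ],
                            n_per_individual = 120, seed = 6)
  expect_equal(nrow(tel), 4 * 120)
  expect_equal(unname(table(tel$animal_id)), rep(120L, 4),
               ignore_attr = TRUE)
  expect_true(all(format(tel$timestamp, "%Y") == "2012"))
  expect_true(min(tel$timestamp) < as.POSIXct("2012-07-01", tz = "UTC"))
  expect_true(max(tel$timestamp) > as.POSIXct("2012-08-31", tz = "UTC"))

  # null selection: points uniform in the disc (chi-squared on 4 quadrants)
  ci <- st$centres[1, ]
  tel1 <- simulate_telemetry(st$rasters, g0[1, , drop = FALSE],
                             st$centres[1, ], n_per_individual = 5000,
                             fix_interval_hours = 0.25, seed = 7)
  dx <- tel1$x - ci$cx; dy <- tel1$y - ci$cy
  expect_true(all(dx^2 + dy^2 <= ci$radius^2))
  quad <- table(dx > 0, dy > 0)
  stat <- sum((quad - 1250)^2 / 1250)
  expect_lt(stat, qchisq(0.99, 3))

  # positive forage selection raises mean forage at used points
  gde <- g0[1, , drop = FALSE]
  gde[, "de"] <- 0.8
  tel_sel <- simulate_telemetry(st$rasters, gde, st$centres[1, ],
                                n_per_individual = 1500,
                                fix_interval_hours = 0.5, seed = 8)
  de_sel <- extract_covariates(tel_sel$x, tel_sel$y, st$rasters$de,
                               st$rasters$lion, st$rasters$wolf)$de
  de_null <- extract_covariates(tel1$x, tel1$y, st$rasters$de,
                                st$rasters$lion, st$rasters$wolf)$de
  expect_gt(mean(de_sel), mean(de_null) + 0.05)
})

test_that("demography defaults hit the calibrated medians and rates", {
  dem <- simulate_demography(n = 10000, seed = 12)
  expect_equal(median(dem$ifbf), 7.5, tolerance = 0.15)
  expect_equal(mean(dem$preg), 0.76, tolerance = 0.03)
  expect_equal(mean(dem$lact), 0.48, tolerance = 0.03)
  diff_lact <- mean(dem$ifbf[dem$lact == 1]) - mean(dem$ifbf[dem$lact == 0])
  expect_equal(diff_lact, -2.89, tolerance = 0.25)
  expect_true(all(dem$ifbf >= 0 & dem$ifbf <= 30))

  # exact propagation without noise
  d0 <- simulate_demography(n = 50, seed = 1,
                            bodyfat = list(alpha = 7.5, pred = 0, lact = 0,
                                           pred_lact = 0, sd = 0))
  expect_true(all(d0$ifbf == 7.5))
})

test_that("a full synthetic study is reproducible and self-consistent", {
  s1 <- simulate_study(n_individuals = 5, n_fixes = 60, seed = 99,
                       landscape = list(n_rows = 96, n_cols = 96))
  s2 <- simulate_study(n_individuals = 5, n_fixes = 60, seed = 99,
                       landscape = list(n_rows = 96, n_cols = 96))
  expect_identical(s1$telemetry, s2$telemetry)
  expect_identical(s1$truth$gamma, s2$truth$gamma)
  expect_setequal(unique(s1$telemetry$animal_id),
                  s1$demography$individual_id)
})
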
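make_toy_table <- function(n = 200, seed = 1, beta = c(0.5, 0.8, -0.5, 0.3,
                                                       -0.2, 0.1)) {
  set.seed(seed)
  d <- data.frame(de = rnorm(n), ml = rnorm(n), wf = rnorm(n))
  X <- cbind(1, d$de, d$ml, d$wf, d$de * d$ml, d$de * d$wf)
  d$used <- rbinom(n, 1, plogis(drop(X %*% beta)))
  d$weight <- 1
  d$individual_id <- "a"
  d
}

test_that("flat-prior fixed-effects MAP equals the logistic MLE", {
  d <- make_toy_table()
  spec <- rsf_model_spec(random = NULL, random_intercept = FALSE,
                         prior_sd_fixed = Inf)
  fit <- fit_hierarchical_rsf(d, spec)
  oracle <- glm(used ~ de * ml + de * wf, binomial, d)
  expect_lt(max(abs(fit$beta - unname(coef(oracle)))), 1e-3)
  # Laplace standard errors match the glm information matrix
  expect_equal(unname(fit$beta_sd), unname(summary(oracle)$coefficients[, 2]),
               tolerance = 1e-4)
})

test_that("the weighted likelihood is invariant to splitting weights", {
  d <- make_toy_table(n = 150)
  d$weight[d$used == 0] <- 100
  spec <- rsf_model_spec(random = NULL, random_intercept = FALSE,
                         prior_sd_fixed = Inf)
  f1 <- fit_hierarchical_rsf(d, spec)
  avail <- d[d$used == 0, ]
  avail$weight <- 50
  d2 <- rbind(transform(d, weight = ifelse(used == 0, 50, weight)), avail)
  f2 <- fit_hierarchical_rsf(d2, spec)
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-6)
})

test_that("hierarchical MAP recovers truth on a simulated study", {
  st <- small_study()
  fit <- small_fit()
  truth <- c(de = 0.2, ml = -0.1, wf = 0.3, "de:ml" = -0.1, "de:wf" = 0.03)
  z <- (fit$beta[-1] - truth) / fit$beta_sd[-1]
  expect_true(all(abs(z) < 3))
  expect_true(all(fit$sigma > 0))
  # hierarchical centering: individual slopes average to the population
  # effect within a few posterior standard errors
  gap <- abs(colMeans(fit$gamma[, -1]) - fit$beta[-1])
  expect_true(all(gap < 3 * fit$sigma / sqrt(length(fit$individuals)) +
                    1e-3))
})

test_that("predictions follow the exponential form at both levels", {
  fit <- small_fit()
  nd <- data.frame(de = c(0, 1), ml = 0, wf = 0)
  w <- predict_relative_use(fit, nd, level = "population")
  expect_equal(w[1], exp(unname(fit$beta["intercept"])))
  expect_equal(w[2] / w[1], exp(unname(fit$beta["de"])))
  expect_true(all(w > 0))
  id <- fit$individuals[3]
  wi <- predict_relative_use(fit, nd, level = "individual", individual = id)
  expect_equal(wi[2] / wi[1], exp(unname(fit$gamma[id, "de"])))
  # monotone in de at fixed risk when the de coefficient is positive
  nd2 <- data.frame(de = seq(-2, 2, 0.5), ml = 0, wf = 0)
  if (fit$beta["de"] > 0)
    expect_true(all(diff(predict_relative_use(fit, nd2)) > 0))
  expect_error(predict_relative_use(fit, nd, level = "individual",
                                    individual = "nobody"), "unknown")
})

test_that("posterior summaries are equal-tailed and equivariant", {
  set.seed(8)
  z <- rnorm(1e5)
  s <- posterior_summary(z)
  expect_equal(unname(s["lower"]), qnorm(0.05), tolerance = 0.02)
  expect_equal(unname(s["upper"]), qnorm(0.95), tolerance = 0.02)
  expect_equal(unname(posterior_summary(rep(3, 100))), c(3, 3, 3))
  expect_equal(posterior_summary(z + 2), s + 2, tolerance = 1e-12)
  expect_error(posterior_summary(numeric(0)), "empty")
})

test_that("the Gibbs sampler agrees with MAP and stores diagnostics", {
  st <- small_study()
  tab <- st$table[st$table$individual_id %in%
                    rownames(st$gamma)[1:6], ]
  map <- fit_hierarchical_rsf(tab, rsf_model_spec(), method = "map")
  mc <- suppressWarnings(
    fit_hierarchical_rsf(tab, rsf_model_spec(), method = "mcmc",
                         chains = 2, iter = 300, warmup = 300, seed = 12))
  expect_true(all(c("rhat", "ess") %in% names(mc$summary)))
  expect_true(all(is.finite(mc$summary$rhat[mc$summary$sd > 1e-8])))
  # posterior means near the MAP for the well-identified slopes
  expect_lt(max(abs(mc$beta[-1] - map$beta[-1])), 0.15)
  # summary means sit inside their own credible intervals
  expect_true(all(mc$summary$mean >= mc$summary$lo90 - 1e-9 &
                    mc$summary$mean <= mc$summary$hi90 + 1e-9))
  # draws are reproducible under the same seed
  mc2 <- suppressWarnings(
    fit_hierarchical_rsf(tab, rsf_model_spec(), method = "mcmc",
                         chains = 2, iter = 300, warmup = 300, seed = 12))
  expect_identical(mc$draws, mc2$draws)
})

test_that("degenerate inputs are rejected", {
  d <- make_toy_table(50)
  d$de[1] <- NA
  expect_error(fit_hierarchical_rsf(d, rsf_model_spec(random = NULL,
                                                      random_intercept = FALSE)),
               "covariate")
  expect_error(fit_hierarchical_rsf(make_toy_table(50), rsf_model_spec()),
               "at least 2 individuals")
  expect_error(rsf_model_spec(random = c("de", "ml")), "random")
})
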
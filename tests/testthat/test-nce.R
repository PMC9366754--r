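make_nce_data <- function(n = 40, seed = 3, b_lact = -2.9, b_ml = 0.5,
                          sd = 2) {
  set.seed(seed)
  d <- data.frame(individual_id = as.character(seq_len(n)),
                  ml = rnorm(n), wf = rnorm(n),
                  lact = rbinom(n, 1, 0.5))
  d$ifbf <- pmin(pmax(9 + b_ml * d$ml + b_lact * d$lact + rnorm(n, 0, sd),
                      0), 30)
  d$preg <- rbinom(n, 1, plogis(1 + 0.3 * d$ml))
  d
}

test_that("flat-prior body-fat posterior matches ordinary least squares", {
  d <- make_nce_data(30)
  fit <- fit_bodyfat_model(d, "ml", prior_sd = Inf, draws = 30000,
                           seed = 10)
  ols <- lm(ifbf ~ ml * lact, d)
  expect_lt(max(abs(fit$coef - unname(coef(ols)))), 0.05)
  # the posterior sd of sigma is positive and the summary is ordered
  s <- fit$summary
  expect_true(all(s$lo90 <= s$mean & s$mean <= s$hi90))
})

test_that("flat-prior pregnancy MAP matches the logistic MLE", {
  d <- make_nce_data(40)
  fit <- fit_pregnancy_model(d, "ml", prior_sd = Inf)
  oracle <- glm(preg ~ ml * lact, binomial, d)
  expect_lt(max(abs(fit$coef - unname(coef(oracle)))), 1e-3)
})

test_that("NCE estimates are invariant to relabelling individuals", {
  d <- make_nce_data(30)
  perm <- d[sample(nrow(d)), ]
  f1 <- fit_bodyfat_model(d, "ml", draws = 5000, seed = 9)
  f2 <- fit_bodyfat_model(perm, "ml", draws = 5000, seed = 9)
  expect_equal(f1$coef, f2$coef, tolerance = 0.05)
  p1 <- fit_pregnancy_model(d, "ml")
  p2 <- fit_pregnancy_model(perm, "ml")
  expect_equal(p1$coef, p2$coef, tolerance = 1e-8)
})

test_that("a constant shift in trade-offs reparameterizes, not refits", {
  d <- make_nce_data(35)
  f1 <- fit_pregnancy_model(d, "ml", prior_sd = Inf)
  d2 <- transform(d, ml = ml + 5)
  f2 <- fit_pregnancy_model(d2, "ml", prior_sd = Inf)
  # slopes in ml are unchanged; intercept and lactation absorb the shift
  expect_equal(unname(f2$coef["ml"]), unname(f1$coef["ml"]),
               tolerance = 1e-4)
  expect_equal(unname(f2$coef["ml:lact"]), unname(f1$coef["ml:lact"]),
               tolerance = 1e-4)
  expect_equal(unname(f2$coef["intercept"]),
               unname(f1$coef["intercept"] - 5 * f1$coef["ml"]),
               tolerance = 1e-4)
  expect_equal(unname(f2$coef["lact"]),
               unname(f1$coef["lact"] - 5 * f1$coef["ml:lact"]),
               tolerance = 1e-4)
})

test_that("constant lactation reduces the model with a warning", {
  d <- make_nce_data(30)
  d$lact <- 1
  expect_warning(fit <- fit_bodyfat_model(d, "ml", seed = 2), "reduced")
  expect_equal(nrow(fit$summary), 3)  # intercept, slope, sigma
})

test_that("complete separation is detected and regularized", {
  d <- data.frame(individual_id = as.character(1:20), ml = 1:20 - 10.5,
                  wf = 0, lact = rep(0:1, 10))
  d$preg <- as.integer(d$ml > 0)
  expect_warning(fit <- fit_pregnancy_model(d, "ml"), "separation")
  expect_true(all(is.finite(fit$coef)))
  expect_lt(max(abs(fit$coef)), 10)   # the Normal(0,2) priors bound it
})

test_that("error paths: too few animals, single pregnancy outcome", {
  d <- make_nce_data(8)
  expect_error(fit_bodyfat_model(d, "ml"), "at least 10")
  d2 <- make_nce_data(20)
  d2$preg <- 1
  expect_error(fit_pregnancy_model(d2, "ml"), "both pregnancy outcomes")
})

test_that("zero-effect simulations give near-nominal credible coverage", {
  cover <- replicate(40, {
    d <- make_nce_data(27, seed = NULL, b_lact = 0, b_ml = 0)
    f <- fit_bodyfat_model(d, "ml", draws = 800, warmup = 100)
    s <- f$summary[f$summary$parameter == "ml", ]
    s$lo90 <= 0 && 0 <= s$hi90
  })
  expect_gte(mean(cover), 0.75)
})
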
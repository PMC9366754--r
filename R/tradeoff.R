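# Per-individual forage-versus-risk trade-off statistics and the downstream
# nonconsumptive-effect (NCE) models for fall body fat and pregnancy.
#
# The trade-off for an individual is the difference in relative use of
# high-quality forage (digestible energy at its 95th percentile) between
# high predator risk (95th percentile) and low predator risk (5th
# percentile), evaluated from that individual's selection coefficients.
# Negative values mean relative use is lower where risk is high: a
# risk-averse trade-off.

#' Compute per-individual forage-risk trade-off statistics
#'
#' For each individual i with coefficient estimates `gamma_i`,
#' `delta_i = w_i(de = q_de, risk = q_hi) - w_i(de = q_de, risk = q_lo)`
#' where `w_i = exp(linear predictor)`, the other predator's covariate sits
#' at 0 (its standardized mean), and quantiles are taken across the pooled
#' design table on the model (standardized) covariate scale.
#'
#' @param fit an `rsf_fit` with per-individual coefficients (normally the
#'   third-order fit).
#' @param table the standardized used-available table supplying the
#'   covariate quantiles.
#' @param predator `"ml"` (mountain lion) or `"wf"` (wolf).
#' @param de_q quantile of digestible energy defining high-quality forage.
#' @param hi_q,lo_q high- and low-risk quantiles of the predator covariate.
#' @param include_intercept include `exp(intercept_i)` in both terms? The
#'   default excludes it: the metric is a difference of relative (not
#'   absolute) use and the intercept only rescales both terms.
#' @param at optional named vector `c(de, hi, lo)` of covariate values to
#'   evaluate at directly, bypassing the quantile computation.
#' @return data.frame with `individual_id` and `tradeoff`; quantiles in
#'   attribute `"quantiles"`.
#' @export
compute_tradeoff <- function(fit, table, predator = c("ml", "wf"),
                             de_q = 0.95, hi_q = 0.95, lo_q = 0.05,
                             include_intercept = FALSE, at = NULL) {
  predator <- match.arg(predator)
  if (is.null(fit$gamma)) stop("fit has no per-individual coefficients")
  if (is.null(at)) {
    q_de <- stats::quantile(table$de, de_q, names = FALSE)
    q_hi <- stats::quantile(table[[predator]], hi_q, names = FALSE)
    q_lo <- stats::quantile(table[[predator]], lo_q, names = FALSE)
  } else {
    q_de <- at[["de"]]; q_hi <- at[["hi"]]; q_lo <- at[["lo"]]
  }
  other <- setdiff(c("ml", "wf"), predator)
  nd <- data.frame(de = c(q_de, q_de), risk = c(q_hi, q_lo), other = 0)
  names(nd) <- c("de", predator, other)
  delta <- vapply(fit$individuals, function(id) {
    wr <- predict_relative_use(fit, nd, level = "individual",
                               individual = id,
                               include_intercept = include_intercept)
    wr[1] - wr[2]
  }, 0)
  out <- data.frame(individual_id = fit$individuals, tradeoff = delta)
  rownames(out) <- NULL
  attr(out, "quantiles") <- c(de = q_de, hi = q_hi, lo = q_lo)
  attr(out, "predator") <- predator
  out
}

#' Join trade-off metrics to demography
#'
#' @param ml,wf trade-off tables from [compute_tradeoff()].
#' @param demography data.frame with `individual_id`, `ifbf` (percent
#'   ingesta-free body fat), `preg` (0/1), `lact` (0/1).
#' @return the trade-off/demography table with columns
#'   `individual_id, ml, wf, ifbf, preg, lact` (inner join on id).
#' @export
tradeoff_demography_table <- function(ml, wf, demography) {
  t1 <- stats::setNames(ml[c("individual_id", "tradeoff")],
                        c("individual_id", "ml"))
  t2 <- stats::setNames(wf[c("individual_id", "tradeoff")],
                        c("individual_id", "wf"))
  demography <- demography[intersect(c("individual_id", "ifbf", "preg",
                                       "lact"), names(demography))]
  out <- merge(merge(t1, t2, by = "individual_id"), demography,
               by = "individual_id")
  if (any(out$ifbf < 0 | out$ifbf > 30, na.rm = TRUE))
    warning("body fat outside the plausible [0, 30] percent range")
  out
}

nce_design <- function(data, predator) {
  tv <- data[[predator]]
  if (any(!is.finite(tv))) stop("non-finite trade-off covariate")
  lact <- data$lact
  if (length(unique(lact)) < 2) {
    warning("lactation status is constant; fitting reduced model without lactation terms")
    X <- cbind(intercept = 1, pred = tv)
  } else {
    X <- cbind(intercept = 1, pred = tv, lact = lact, pred_lact = tv * lact)
  }
  colnames(X) <- sub("^pred$", predator, colnames(X))
  colnames(X) <- sub("^pred_lact$", paste0(predator, ":lact"), colnames(X))
  X
}

nce_summary <- function(draws_mat) {
  qs <- t(apply(draws_mat, 2, stats::quantile, c(0.05, 0.95), names = FALSE))
  data.frame(parameter = colnames(draws_mat), mean = colMeans(draws_mat),
             sd = apply(draws_mat, 2, stats::sd),
             lo90 = qs[, 1], hi90 = qs[, 2], row.names = NULL)
}

#' Bayesian linear model of fall body fat on a trade-off metric
#'
#' `ifbf_i = a + b_pred pred_i + b_lact lact_i + b_pred:lact pred_i lact_i
#' + e_i`, Gaussian errors; coefficients get Normal(0, `prior_sd`) priors
#' (standard deviations) and the error scale a flat prior. Sampled by a
#' conjugate Gibbs sampler (exact conditional draws).
#'
#' @param data trade-off/demography table
#'   (see [tradeoff_demography_table()]).
#' @param predator `"ml"` or `"wf"`: which trade-off column is the covariate.
#' @param prior_sd prior standard deviation of the coefficients
#'   (default 100; `Inf` for flat priors).
#' @param draws,warmup Gibbs draws kept and discarded.
#' @param seed integer seed.
#' @return object of class `nce_fit`: `summary` (mean, sd, 90% CrI for the
#'   coefficients and `sigma`), `draws`, `coef` (posterior means).
#' @export
fit_bodyfat_model <- function(data, predator = c("ml", "wf"),
                              prior_sd = 100, draws = 2000, warmup = 200,
                              seed = NULL) {
  predator <- match.arg(predator)
  if (nrow(data) < 10) stop("need at least 10 animals for the body-fat model")
  X <- nce_design(data, predator)
  y <- data$ifbf
  n <- length(y); p <- ncol(X)
  local_seed(seed)
  P <- diag(if (is.finite(prior_sd)) 1 / prior_sd^2 else 0, p)
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y))
  beta <- drop(solve(XtX + P, Xty))            # start near the ridge fit
  out <- matrix(NA_real_, draws, p + 1,
                dimnames = list(NULL, c(colnames(X), "sigma")))
  sig2 <- max(stats::var(y - drop(X %*% beta)), 1e-8)
  for (it in seq_len(warmup + draws)) {
    V <- solve(XtX / sig2 + P)
    V <- (V + t(V)) / 2
    m <- drop(V %*% Xty) / sig2
    beta <- drop(m + t(chol(V)) %*% stats::rnorm(p))
    S <- sum((y - drop(X %*% beta))^2)
    sig2 <- S / (2 * stats::rgamma(1, (n - 1) / 2, 1))
    if (it > warmup) out[it - warmup, ] <- c(beta, sqrt(sig2))
  }
  structure(list(model = "bodyfat", predator = predator,
                 summary = nce_summary(out), draws = out,
                 coef = colMeans(out[, seq_len(p), drop = FALSE]),
                 n = n, seed = seed),
            class = "nce_fit")
}

#' Bayesian logistic model of pregnancy on a trade-off metric
#'
#' `logit P(preg_i = 1) = a + b_pred pred_i + b_lact lact_i +
#' b_pred:lact pred_i lact_i` with Normal(0, `prior_sd`) coefficient priors
#' (standard deviations). Estimated at the posterior mode with a Laplace
#' Gaussian approximation (`method = "map"`, default) or by random-walk
#' Metropolis started and scaled at the Laplace fit (`method = "mcmc"`).
#' Complete separation is detected from an unpenalized probe fit and
#' reported; the priors still regularize the returned fit.
#'
#' @inheritParams fit_bodyfat_model
#' @param prior_sd prior standard deviation of coefficients (default 2).
#' @param method `"map"` or `"mcmc"`.
#' @return object of class `nce_fit`.
#' @export
fit_pregnancy_model <- function(data, predator = c("ml", "wf"),
                                prior_sd = 2, method = c("map", "mcmc"),
                                draws = 4000, warmup = 500, seed = NULL) {
  predator <- match.arg(predator)
  method <- match.arg(method)
  X <- nce_design(data, predator)
  y <- data$preg
  if (length(unique(y)) < 2)
    stop("both pregnancy outcomes must be present")
  p <- ncol(X)
  w1 <- rep(1, length(y))
  probe <- newton_wlogit(X, y, w1, rep(0, p), rep(0, p), max_iter = 30)
  if (max(abs(probe$coef)) > 15)
    warning("possible complete separation in the pregnancy data; estimates rely on the priors")
  prec <- rep(if (is.finite(prior_sd)) 1 / prior_sd^2 else 0, p)
  fit <- newton_wlogit(X, y, w1, rep(0, p), prec)
  V <- solve(fit$hessian); V <- (V + t(V)) / 2
  if (method == "map") {
    sds <- sqrt(diag(V))
    z <- stats::qnorm(0.95)
    summ <- data.frame(parameter = colnames(X), mean = fit$coef, sd = sds,
                       lo90 = fit$coef - z * sds, hi90 = fit$coef + z * sds,
                       row.names = NULL)
    return(structure(list(model = "pregnancy", predator = predator,
                          summary = summ, draws = NULL,
                          coef = stats::setNames(fit$coef, colnames(X)),
                          n = length(y), seed = seed),
                     class = "nce_fit"))
  }
  local_seed(seed)
  L <- t(chol(V)) * (2.38 / sqrt(p))
  b <- fit$coef
  logpost <- function(b) wbl_loglik(drop(X %*% b), y, w1) -
    0.5 * sum(prec * b^2)
  lp <- logpost(b)
  out <- matrix(NA_real_, draws, p, dimnames = list(NULL, colnames(X)))
  for (it in seq_len(warmup + draws)) {
    prop <- b + drop(L %*% stats::rnorm(p))
    lp_prop <- logpost(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      b <- prop; lp <- lp_prop
    }
    if (it > warmup) out[it - warmup, ] <- b
  }
  structure(list(model = "pregnancy", predator = predator,
                 summary = nce_summary(out), draws = out,
                 coef = colMeans(out), n = length(y), seed = seed),
            class = "nce_fit")
}

#' @export
print.nce_fit <- function(x, ...) {
  cat(sprintf("nce_fit (%s, %s trade-off, n = %d)\n", x$model, x$predator,
              x$n))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write NCE posterior summaries as JSON
#' @param fits named list of `nce_fit` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nce_report <- function(fits, path) {
  rep <- lapply(fits, function(f) {
    s <- split(f$summary[c("mean", "sd", "lo90", "hi90")],
               f$summary$parameter)
    list(model = f$model, predator = f$predator, n = f$n,
         parameters = lapply(s, as.list))
  })
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
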
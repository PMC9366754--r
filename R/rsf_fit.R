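# Weighted hierarchical Bayesian resource selection functions.
#
# Model: relative use at location j for individual i is
#   w(x_ij) = exp(g0_i + g_de_i de_j + g_ml_i ml_j + g_wf_i wf_j
#                 + g_de:ml_i de_j ml_j + g_de:wf_i de_j wf_j)
# estimated from the used-available contrast with a weighted Bernoulli-logit
# likelihood (each row's log-likelihood multiplied by its weight; available
# rows get a large weight so the fit approximates the point-process
# likelihood). Individual coefficients are hierarchically centred:
#   g_cov,i ~ Normal(beta_cov, sigma_cov),  sigma_cov ~ Uniform(0, upper)
# and random intercepts g0_i ~ Normal(beta_0, sd fixed at 100), the fixed
# scale chosen to avoid shrinking intercepts that absorb unequal exposure.
# Population effects beta get Normal(0, 2) priors (scales are standard
# deviations throughout).
#
# Two estimation modes are provided: "map" (block coordinate ascent to the
# joint posterior mode with a Laplace Gaussian approximation for intervals)
# and "mcmc" (Metropolis-within-Gibbs: random-walk Metropolis on each
# individual's coefficient block with Laplace-calibrated proposals, exact
# Gibbs draws for beta, exact truncated inverse-gamma Gibbs draws for the
# random-effect scales).

#' Specify the RSF model
#'
#' @param covariates model terms besides the intercept; `"a:b"` denotes a
#'   product of standardized main effects.
#' @param random covariates that get per-individual random slopes. Either
#'   identical to `covariates` (the full hierarchical model) or `NULL`
#'   (fixed effects only); partial structures are not supported.
#' @param random_intercept per-individual random intercepts?
#' @param prior_sd_fixed prior standard deviation of the population
#'   (fixed-effect) coefficients; `Inf` gives flat priors.
#' @param sigma_upper upper bound of the Uniform prior on random-slope
#'   standard deviations.
#' @param intercept_re_sd fixed standard deviation of the random intercepts
#'   (not estimated).
#' @param weight_available the available-row weight the design tables are
#'   expected to carry (recorded for provenance; the fit uses the table's
#'   `weight` column).
#' @return an object of class `rsf_spec`.
#' @export
rsf_model_spec <- function(covariates = c("de", "ml", "wf", "de:ml", "de:wf"),
                           random = covariates,
                           random_intercept = !is.null(random),
                           prior_sd_fixed = 2,
                           sigma_upper = 2,
                           intercept_re_sd = 100,
                           weight_available = 1000) {
  if (!is.null(random) && !setequal(random, covariates))
    stop("random must equal covariates (full hierarchical model) or be NULL")
  structure(list(covariates = covariates, random = random,
                 random_intercept = random_intercept,
                 prior_sd_fixed = prior_sd_fixed, sigma_upper = sigma_upper,
                 intercept_re_sd = intercept_re_sd,
                 weight_available = weight_available),
            class = "rsf_spec")
}

# model matrix from covariate columns; interactions are products of columns
rsf_design_matrix <- function(data, covariates) {
  cols <- lapply(covariates, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, function(p) {
      v <- data[[p]]
      if (is.null(v)) stop("covariate column not found: ", p)
      v
    }))
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("intercept", covariates)
  if (any(!is.finite(X))) stop("non-finite covariate values in design matrix")
  X
}

# weighted bernoulli-logit log-likelihood
wbl_loglik <- function(eta, y, w) sum(w * (y * eta - log1pexp(eta)))

# Newton maximizer of the weighted logistic log-likelihood plus Gaussian
# prior N(prior_mean, diag(1/prior_prec)); prior_prec may contain zeros.
newton_wlogit <- function(X, y, w, prior_mean, prior_prec, start = NULL,
                          max_iter = 50, tol = 1e-10) {
  p <- ncol(X)
  b <- if (is.null(start)) rep(0, p) else start
  P <- diag(prior_prec, p)
  obj <- function(b) {
    wbl_loglik(drop(X %*% b), y, w) -
      0.5 * sum(prior_prec * (b - prior_mean)^2)
  }
  f <- obj(b)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- expit(eta)
    g <- drop(crossprod(X, w * (y - mu))) - prior_prec * (b - prior_mean)
    H <- crossprod(X * sqrt(w * mu * (1 - mu))) + P
    step <- tryCatch(solve(H, g), error = function(e) g / (diag(H) + 1e-8))
    sz <- 1
    repeat {
      b_new <- b + sz * step
      f_new <- obj(b_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-8) { b_new <- b; f_new <- f; break }
    }
    moved <- max(abs(b_new - b))
    b <- b_new; f <- f_new
    if (moved < tol) break
  }
  eta <- drop(X %*% b)
  mu <- expit(eta)
  H <- crossprod(X * sqrt(w * mu * (1 - mu))) + P
  list(coef = b, hessian = H, logpost = f, iterations = it)
}

# split data by individual into blocks the samplers reuse
rsf_blocks <- function(table, spec) {
  X <- rsf_design_matrix(table, spec$covariates)
  y <- as.numeric(table$used)
  w <- as.numeric(table$weight)
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  id <- as.character(table$individual_id)
  ids <- unique(id)
  blocks <- lapply(ids, function(i) {
    k <- which(id == i)
    list(X = X[k, , drop = FALSE], y = y[k], w = w[k])
  })
  names(blocks) <- ids
  list(X = X, y = y, w = w, ids = ids, blocks = blocks,
       coef_names = colnames(X))
}

# prior sd per coefficient for the individual-level conditional given sigma
gamma_prior_sd <- function(sigma, spec) {
  c(spec$intercept_re_sd, sigma)
}

#' Fit the weighted hierarchical RSF
#'
#' @param table a standardized used-available table
#'   (see [standardize_covariates()]) with columns `individual_id`, `used`,
#'   `weight` and the model covariates.
#' @param spec an [rsf_model_spec()].
#' @param method `"map"` (posterior mode + Laplace intervals; fast) or
#'   `"mcmc"` (full posterior draws).
#' @param chains,iter,warmup MCMC settings (`iter` post-warmup draws per
#'   chain).
#' @param seed integer seed for the sampler.
#' @param control list; `sigma_init`, `sigma_floor`, `max_em_iter`, `tol`.
#' @return an object of class `rsf_fit` with population coefficients
#'   (`beta`), random-effect scales (`sigma`), per-individual coefficients
#'   (`gamma`), a `summary` data.frame (mean, sd, 90% credible interval,
#'   rhat, ess), and for `method = "mcmc"` the raw `draws`.
#' @export
fit_hierarchical_rsf <- function(table, spec = rsf_model_spec(),
                                 method = c("map", "mcmc"),
                                 chains = 4, iter = 1000, warmup = 1000,
                                 seed = NULL, control = list()) {
  method <- match.arg(method)
  ctl <- utils::modifyList(list(sigma_init = 0.25, sigma_floor = 1e-3,
                                max_em_iter = 100, tol = 1e-6), control)
  dat <- rsf_blocks(table, spec)
  p <- length(dat$coef_names)
  hier <- !is.null(spec$random) || spec$random_intercept
  if (hier && length(dat$ids) < 2)
    stop("hierarchical fit requires at least 2 individuals")

  if (!hier) {
    prior_prec <- rep(if (is.finite(spec$prior_sd_fixed))
      1 / spec$prior_sd_fixed^2 else 0, p)
    fit <- newton_wlogit(dat$X, dat$y, dat$w, rep(0, p), prior_prec)
    V <- solve(fit$hessian)
    sds <- sqrt(diag(V))
    z <- stats::qnorm(0.95)
    summ <- data.frame(parameter = paste0("beta_", dat$coef_names),
                       mean = fit$coef, sd = sds,
                       lo90 = fit$coef - z * sds, hi90 = fit$coef + z * sds,
                       rhat = NA_real_, ess = NA_real_)
    return(new_rsf_fit(spec, method, dat, beta = fit$coef, beta_sd = sds,
                       sigma = NULL, sigma_sd = NULL, gamma = NULL,
                       gamma_sd = NULL, summary = summ, draws = NULL,
                       logpost = fit$logpost, table = table, seed = seed))
  }

  map <- rsf_map(dat, spec, ctl)
  if (method == "map") {
    return(rsf_fit_from_map(map, dat, spec, table, seed))
  }
  rsf_mcmc(dat, spec, map, chains = chains, iter = iter, warmup = warmup,
           seed = seed, table = table, ctl = ctl)
}

# --- MAP: block coordinate ascent -------------------------------------------

rsf_map <- function(dat, spec, ctl) {
  p <- length(dat$coef_names)
  n_ind <- length(dat$ids)
  beta <- rep(0, p)
  sigma <- rep(ctl$sigma_init, p - 1)           # slopes only
  gamma <- matrix(0, n_ind, p,
                  dimnames = list(dat$ids, dat$coef_names))
  prior_prec_beta <- rep(if (is.finite(spec$prior_sd_fixed))
    1 / spec$prior_sd_fixed^2 else 0, p)
  V <- matrix(0, n_ind, p)
  for (em in seq_len(ctl$max_em_iter)) {
    old <- c(beta, sigma)
    sd_g <- gamma_prior_sd(sigma, spec)
    prec_g <- 1 / sd_g^2
    for (i in seq_len(n_ind)) {
      b <- dat$blocks[[i]]
      nf <- newton_wlogit(b$X, b$y, b$w, beta, prec_g,
                          start = gamma[i, ], max_iter = 25)
      gamma[i, ] <- nf$coef
      V[i, ] <- diag(solve(nf$hessian))
    }
    # beta_c | gamma: quadratic => closed form
    beta <- (colSums(gamma) * prec_g) / (n_ind * prec_g + prior_prec_beta)
    # sigma: Laplace-EM update of the marginal mode; the conditional
    # variance of each gamma enters so weakly informed individuals do not
    # collapse sigma to zero
    S <- colSums(sweep(gamma[, -1, drop = FALSE], 2, beta[-1])^2 +
                   V[, -1, drop = FALSE])
    sigma <- pmin(pmax(sqrt(S / n_ind), ctl$sigma_floor), spec$sigma_upper)
    if (max(abs(c(beta, sigma) - old)) < ctl$tol) break
  }
  # final gamma refresh at converged (beta, sigma)
  sd_g <- gamma_prior_sd(sigma, spec)
  prec_g <- 1 / sd_g^2
  A_inv <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    b <- dat$blocks[[i]]
    nf <- newton_wlogit(b$X, b$y, b$w, beta, prec_g, start = gamma[i, ],
                        max_iter = 25)
    gamma[i, ] <- nf$coef
    A_inv[[i]] <- solve(nf$hessian)
  }
  # Laplace: Schur complement for Cov(beta); gamma marginals via the
  # cross-blocks (gamma_i couples to beta only through the prior precision D)
  D <- diag(prec_g, p)
  H_bb <- diag(n_ind * prec_g + prior_prec_beta, p)
  S_bb <- H_bb - Reduce(`+`, lapply(A_inv, function(Ai) D %*% Ai %*% D))
  V_beta <- solve((S_bb + t(S_bb)) / 2)
  gamma_sd <- t(vapply(A_inv, function(Ai) {
    M <- Ai %*% D
    sqrt(pmax(diag(Ai + M %*% V_beta %*% t(M)), 0))
  }, numeric(p)))
  dimnames(gamma_sd) <- dimnames(gamma)
  list(beta = beta, sigma = sigma, gamma = gamma,
       V_beta = V_beta, beta_sd = sqrt(pmax(diag(V_beta), 0)),
       sigma_sd = sigma / sqrt(2 * n_ind),
       gamma_sd = gamma_sd, A_inv = A_inv, em_iterations = em)
}

rsf_fit_from_map <- function(map, dat, spec, table, seed) {
  p <- length(dat$coef_names)
  z <- stats::qnorm(0.95)
  summ <- data.frame(
    parameter = c(paste0("beta_", dat$coef_names),
                  paste0("sigma_", dat$coef_names[-1])),
    mean = c(map$beta, map$sigma),
    sd = c(map$beta_sd, map$sigma_sd),
    rhat = NA_real_, ess = NA_real_)
  summ$lo90 <- summ$mean - z * summ$sd
  summ$hi90 <- summ$mean + z * summ$sd
  summ$lo90[seq(p + 1, nrow(summ))] <- pmax(summ$lo90[seq(p + 1, nrow(summ))], 0)
  summ <- summ[, c("parameter", "mean", "sd", "lo90", "hi90", "rhat", "ess")]
  new_rsf_fit(spec, "map", dat, beta = map$beta, beta_sd = map$beta_sd,
              sigma = map$sigma, sigma_sd = map$sigma_sd,
              gamma = map$gamma, gamma_sd = map$gamma_sd, summary = summ,
              draws = NULL, logpost = NA_real_, table = table, seed = seed,
              extra = list(em_iterations = map$em_iterations))
}

# --- MCMC: Metropolis-within-Gibbs ------------------------------------------

rsf_mcmc <- function(dat, spec, map, chains, iter, warmup, seed, table, ctl) {
  local_seed(seed)
  p <- length(dat$coef_names)
  n_ind <- length(dat$ids)
  prior_prec_beta <- rep(if (is.finite(spec$prior_sd_fixed))
    1 / spec$prior_sd_fixed^2 else 0, p)
  # proposal scales from the per-individual Laplace blocks
  props <- lapply(map$A_inv, function(Ai)
    t(chol((Ai + t(Ai)) / 2 + diag(1e-10, p))) * (2.38 / sqrt(p)))
  n_par <- p + (p - 1) + n_ind * p
  par_names <- c(paste0("beta_", dat$coef_names),
                 paste0("sigma_", dat$coef_names[-1]),
                 as.vector(outer(dat$ids, dat$coef_names,
                                 function(i, cc) paste0("gamma[", i, "]_", cc))))
  draws <- array(NA_real_, c(iter, chains, n_par))
  accept <- matrix(0, chains, n_ind)
  for (ch in seq_len(chains)) {
    gamma <- map$gamma + matrix(stats::rnorm(n_ind * p, 0, 0.05), n_ind, p)
    beta <- map$beta + stats::rnorm(p, 0, 0.05)
    sigma <- pmin(pmax(map$sigma * exp(stats::rnorm(p - 1, 0, 0.1)),
                       0.01), spec$sigma_upper - 1e-6)
    ll <- vapply(seq_len(n_ind), function(i) {
      b <- dat$blocks[[i]]
      wbl_loglik(drop(b$X %*% gamma[i, ]), b$y, b$w)
    }, 0)
    for (it in seq_len(warmup + iter)) {
      sd_g <- gamma_prior_sd(sigma, spec)
      for (i in seq_len(n_ind)) {
        b <- dat$blocks[[i]]
        prop <- gamma[i, ] + drop(props[[i]] %*% stats::rnorm(p))
        ll_prop <- wbl_loglik(drop(b$X %*% prop), b$y, b$w)
        lr <- ll_prop - ll[i] +
          sum(stats::dnorm(prop, beta, sd_g, log = TRUE)) -
          sum(stats::dnorm(gamma[i, ], beta, sd_g, log = TRUE))
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          gamma[i, ] <- prop; ll[i] <- ll_prop
          if (it > warmup) accept[ch, i] <- accept[ch, i] + 1
        }
      }
      # beta | gamma, sigma  (exact Gaussian)
      prec_g <- 1 / sd_g^2
      v <- 1 / (n_ind * prec_g + prior_prec_beta)
      beta <- stats::rnorm(p, colSums(gamma) * prec_g * v, sqrt(v))
      # sigma_c | gamma, beta  (exact: truncated inverse-gamma)
      S <- pmax(colSums(sweep(gamma[, -1, drop = FALSE], 2, beta[-1])^2),
                1e-12)
      shape <- (n_ind - 1) / 2
      tau_min <- 1 / spec$sigma_upper^2
      u_lo <- stats::pgamma(tau_min, shape, rate = S / 2)
      u <- stats::runif(p - 1, u_lo, 1)
      tau <- stats::qgamma(pmin(u, 1 - 1e-15), shape, rate = S / 2)
      sigma <- 1 / sqrt(pmax(tau, tau_min))
      if (it > warmup)
        draws[it - warmup, ch, ] <- c(beta, sigma, as.vector(gamma))
    }
  }
  acc_rate <- accept / iter
  if (any(acc_rate < 0.05))
    warning(sprintf("poor mixing: %d individual block(s) accepted < 5%% of proposals",
                    sum(acc_rate < 0.05)))
  flat <- matrix(aperm(draws, c(1, 2, 3)), iter * chains, n_par)
  colnames(flat) <- par_names
  rhat <- apply(draws, 3, split_rhat)
  ess <- apply(draws, 3, ess_basic)
  if (any(rhat > 1.05, na.rm = TRUE))
    warning(sprintf("convergence: %d parameter(s) have potential scale reduction > 1.05",
                    sum(rhat > 1.05, na.rm = TRUE)))
  qs <- t(apply(flat, 2, stats::quantile, c(0.05, 0.95), names = FALSE))
  summ <- data.frame(parameter = par_names, mean = colMeans(flat),
                     sd = apply(flat, 2, stats::sd),
                     lo90 = qs[, 1], hi90 = qs[, 2], rhat = rhat, ess = ess)
  rownames(summ) <- NULL
  bi <- seq_len(p); si <- p + seq_len(p - 1)
  gamma_mean <- matrix(colMeans(flat[, -c(bi, si), drop = FALSE]), n_ind, p,
                       dimnames = list(dat$ids, dat$coef_names))
  gamma_sd <- matrix(apply(flat[, -c(bi, si), drop = FALSE], 2, stats::sd),
                     n_ind, p, dimnames = list(dat$ids, dat$coef_names))
  new_rsf_fit(spec, "mcmc", dat, beta = colMeans(flat[, bi, drop = FALSE]),
              beta_sd = apply(flat[, bi, drop = FALSE], 2, stats::sd),
              sigma = colMeans(flat[, si, drop = FALSE]),
              sigma_sd = apply(flat[, si, drop = FALSE], 2, stats::sd),
              gamma = gamma_mean, gamma_sd = gamma_sd, summary = summ,
              draws = flat, logpost = NA_real_, table = table, seed = seed,
              extra = list(acceptance = acc_rate, chains = chains,
                           iter = iter, warmup = warmup))
}

new_rsf_fit <- function(spec, method, dat, beta, beta_sd, sigma, sigma_sd,
                        gamma, gamma_sd, summary, draws, logpost, table,
                        seed, extra = list()) {
  names(beta) <- names(beta_sd) <- dat$coef_names
  if (!is.null(sigma)) names(sigma) <- names(sigma_sd) <- dat$coef_names[-1]
  structure(c(list(spec = spec, method = method,
                   coef_names = dat$coef_names, individuals = dat$ids,
                   beta = beta, beta_sd = beta_sd,
                   sigma = sigma, sigma_sd = sigma_sd,
                   gamma = gamma, gamma_sd = gamma_sd,
                   summary = summary, draws = draws, logpost = logpost,
                   standardization = attr(table, "standardization"),
                   seed = seed), extra),
            class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("rsf_fit (%s): %d individuals, terms: %s\n", x$method,
              length(x$individuals), paste(x$coef_names, collapse = ", ")))
  k <- grepl("^(beta|sigma)_", x$summary$parameter)
  print(x$summary[k, ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict relative use from a fitted RSF
#'
#' Evaluates `exp(linear predictor)` for new covariate rows on the model's
#' standardized scale. Population-level predictions use the population
#' coefficients only; individual-level predictions use that individual's
#' coefficient estimates.
#'
#' @param fit an `rsf_fit`.
#' @param newdata data.frame with the model's covariate columns
#'   (standardized scale).
#' @param level `"population"` or `"individual"`.
#' @param individual individual id (required for `level = "individual"`).
#' @param include_intercept multiply by `exp(intercept)`? The intercept only
#'   rescales relative use; excluding it gives predictions anchored at
#'   covariates = 0.
#' @return numeric vector of strictly positive relative-use values.
#' @export
predict_relative_use <- function(fit, newdata,
                                 level = c("population", "individual"),
                                 individual = NULL, include_intercept = TRUE) {
  level <- match.arg(level)
  X <- rsf_design_matrix(newdata, fit$spec$covariates)
  coefs <- if (level == "population") fit$beta else {
    if (is.null(individual) || !(individual %in% rownames(fit$gamma)))
      stop("unknown individual id: ", individual)
    fit$gamma[individual, ]
  }
  if (!include_intercept) coefs["intercept"] <- 0
  exp(drop(X %*% coefs))
}

#' Summarize posterior draws
#'
#' Mean and equal-tailed credible interval (quantiles at `(1 - level)/2` and
#' `1 - (1 - level)/2`).
#'
#' @param draws numeric vector of posterior draws.
#' @param level interval mass (default 0.90).
#' @return named numeric vector `c(mean, lower, upper)`.
#' @export
posterior_summary <- function(draws, level = 0.90) {
  if (!length(draws)) stop("empty draws")
  a <- (1 - level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), names = FALSE)
  c(mean = mean(draws), lower = q[1], upper = q[2])
}

# --- convergence diagnostics -------------------------------------------------

# split potential scale reduction over an iter x chains matrix
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  h <- floor(n / 2)
  sub <- cbind(x[seq_len(h), , drop = FALSE],
               x[seq(n - h + 1, n), , drop = FALSE])
  m <- ncol(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2, stats::var)
  W <- mean(s2)
  B <- h * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((h - 1) / h * W + B / h) / W)
}

# effective sample size from pooled autocorrelations (initial positive
# sequence estimator)
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  rho_sum <- 0
  for (ch in seq_len(m)) {
    v <- x[, ch] - mean(x[, ch])
    s2 <- sum(v^2) / n
    if (s2 <= 0) next
    ac <- stats::acf(x[, ch], lag.max = min(n - 1, 200), plot = FALSE,
                     demean = TRUE)$acf[-1]
    s <- 0
    for (k in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[k] + ac[k + 1]
      if (is.na(pair) || pair <= 0) break
      s <- s + pair
    }
    rho_sum <- rho_sum + s
  }
  rho <- rho_sum / m
  n * m / (1 + 2 * rho)
}
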
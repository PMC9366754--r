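# Synthetic landscapes, individuals, telemetry and demography with the
# statistical structure the analysis assumes: spatially smooth covariate
# fields with a controlled forage-predator correlation, heterogeneous
# individual selection coefficients, GPS fixes drawn proportional to
# exp(linear predictor) inside disc-shaped home ranges, and demography from
# the body-fat/pregnancy models.

gaussian_smooth <- function(M, len) {
  sm <- function(n) {
    K <- outer(seq_len(n), seq_len(n), function(i, j)
      exp(-0.5 * ((i - j) / len)^2))
    K / rowSums(K)
  }
  sm(nrow(M)) %*% M %*% t(sm(ncol(M)))
}

standardize_field <- function(M) (M - mean(M)) / stats::sd(M)

#' Generate synthetic forage and predator-risk landscapes
#'
#' Digestible energy is a smoothed Gaussian random field rescaled to a
#' realistic kcal/g range. Each predator's relative-use surface is
#' `exp(mix * zDE + sqrt(1 - mix^2) * zI)` where `zDE` is the standardized
#' forage field and `zI` an independent standardized smooth field
#' residualized against `zDE`, so the realized correlation between the
#' log-predator covariate and the forage field equals `mix` exactly
#' (squared correlation `mix^2`). `mix = sqrt(0.35) ~ 0.59` reproduces the
#' second-order lion-forage squared correlation of about .35; `sqrt(0.15)`
#' the wolf value of about .15.
#'
#' @param n_rows,n_cols grid size.
#' @param cell_size cell edge (m).
#' @param origin_x,origin_y lower-left corner (m).
#' @param smoothness Gaussian smoothing length in cells.
#' @param mix_lion,mix_wolf mixing coefficients in `[0, 1)`.
#' @param de_range range (kcal/g) the forage field is rescaled to.
#' @param seed integer seed.
#' @return list with [raster_surface()] elements `de`, `lion`, `wolf`.
#' @export
generate_landscapes <- function(n_rows = 256, n_cols = 256, cell_size = 250,
                                origin_x = 0, origin_y = 0, smoothness = 3,
                                mix_lion = sqrt(0.35), mix_wolf = sqrt(0.15),
                                de_range = c(0.5, 3.0), seed = NULL) {
  if (n_rows < 2 || n_cols < 2) stop("grid must be at least 2 x 2")
  if (mix_lion < 0 || mix_lion >= 1 || mix_wolf < 0 || mix_wolf >= 1)
    stop("mix coefficients must be in [0, 1)")
  local_seed(seed)
  noise <- function() matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  z_de <- standardize_field(gaussian_smooth(noise(), smoothness))
  mix_field <- function(mix) {
    z <- standardize_field(gaussian_smooth(noise(), smoothness))
    e <- standardize_field(z - stats::cov(as.vector(z), as.vector(z_de)) /
                             stats::var(as.vector(z_de)) * z_de)
    mix * z_de + sqrt(1 - mix^2) * e
  }
  de_vals <- de_range[1] + (z_de - min(z_de)) / diff(range(z_de)) *
    diff(de_range)
  mk <- function(v) raster_surface(v, origin_x, origin_y, cell_size)
  list(de = mk(de_vals),
       lion = mk(exp(mix_field(mix_lion))),
       wolf = mk(exp(mix_field(mix_wolf))))
}

#' Draw heterogeneous individual selection coefficients
#'
#' Individual coefficients are exact draws from the hierarchically centred
#' model: `gamma_cov,i ~ Normal(beta_cov, sigma_cov)`.
#'
#' @param n_individuals number of individuals.
#' @param beta named population coefficients
#'   (`intercept, de, ml, wf, de:ml, de:wf`).
#' @param sigma named random-effect standard deviations for the slopes.
#' @param sigma_intercept standard deviation of random intercepts in the
#'   generator (a generator choice; unrelated to the fixed prior scale used
#'   when fitting).
#' @param seed integer seed.
#' @return matrix `n_individuals x 6` with individual ids as rownames.
#' @export
draw_individual_coefficients <- function(n_individuals,
                                         beta = c(intercept = 0, de = 0.2,
                                                  ml = -0.1, wf = 0.3,
                                                  "de:ml" = -0.1,
                                                  "de:wf" = 0.03),
                                         sigma = c(de = 0.15, ml = 0.15,
                                                   wf = 0.15, "de:ml" = 0.15,
                                                   "de:wf" = 0.15),
                                         sigma_intercept = 0.5, seed = NULL) {
  if (n_individuals < 1) stop("need at least one individual")
  if (any(sigma < 0) || sigma_intercept < 0)
    stop("random-effect standard deviations must be >= 0")
  local_seed(seed)
  sds <- c(sigma_intercept, sigma[c("de", "ml", "wf", "de:ml", "de:wf")])
  mns <- beta[c("intercept", "de", "ml", "wf", "de:ml", "de:wf")]
  g <- sapply(seq_along(mns), function(j)
    stats::rnorm(n_individuals, mns[j], sds[j]))
  g <- matrix(g, nrow = n_individuals)
  dimnames(g) <- list(sprintf("elk%02d", seq_len(n_individuals)),
                      c("intercept", "de", "ml", "wf", "de:ml", "de:wf"))
  g
}

#' Place disc home ranges inside a landscape
#'
#' Centres are jittered uniformly inside the raster extent inset by the
#' disc radius plus a margin.
#'
#' @param n number of individuals.
#' @param rasters landscape list from [generate_landscapes()].
#' @param radius disc radius (m).
#' @param margin extra inset from the raster edge (m).
#' @param seed integer seed.
#' @return data.frame `individual_id, cx, cy, radius`.
#' @export
simulate_home_centres <- function(n, rasters, radius = 3000, margin = 500,
                                  seed = NULL) {
  local_seed(seed)
  ext <- raster_extent(rasters$de)
  inset <- radius + margin
  if (ext["xmax"] - ext["xmin"] <= 2 * inset ||
      ext["ymax"] - ext["ymin"] <= 2 * inset)
    stop("landscape too small for the requested home-range radius")
  data.frame(individual_id = sprintf("elk%02d", seq_len(n)),
             cx = stats::runif(n, ext["xmin"] + inset, ext["xmax"] - inset),
             cy = stats::runif(n, ext["ymin"] + inset, ext["ymax"] - inset),
             radius = radius)
}

# cells whose centre lies within the disc, with raw covariates
disc_cells <- function(rasters, cx, cy, radius) {
  co <- raster_coords(rasters$de)
  ix <- which(abs(co$x - cx) <= radius)
  iy <- which(abs(co$y - cy) <= radius)
  g <- expand.grid(x = co$x[ix], y = co$y[iy])
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  cov <- extract_covariates(g$x, g$y, rasters$de, rasters$lion, rasters$wolf)
  list(x = g$x, y = g$y, cov = cov)
}

# covariate moments pooled over all individuals' disc cells; the generator
# defines its truth coefficients on this standardized scale so fitted
# population effects are directly comparable to the generating values
disc_standardization <- function(cells) {
  pooled <- do.call(rbind, lapply(cells, `[[`, "cov"))
  lapply(pooled, function(v) c(mean = mean(v), sd = stats::sd(v)))
}

apply_standardization <- function(cov, constants) {
  for (cc in names(constants))
    cov[[cc]] <- (cov[[cc]] - constants[[cc]]["mean"]) / constants[[cc]]["sd"]
  cov
}

#' Simulate GPS telemetry from individual selection surfaces
#'
#' Fixes are drawn inside each individual's disc home range with density
#' proportional to `exp(gamma_i . x)` by rejection sampling (uniform
#' proposals in the disc, acceptance `exp(eta - eta_max)` with the maximum
#' taken over disc cells). Timestamps sit on a regular fix schedule spanning
#' the simulation window, so the season and rest-window filters have
#' something to remove.
#'
#' @param rasters landscape list from [generate_landscapes()].
#' @param gamma coefficient matrix from [draw_individual_coefficients()];
#'   coefficients act on the standardized covariate scale (moments pooled
#'   over all individuals' disc cells), the same scale the fitting stage
#'   standardizes to.
#' @param centres home-range placements from [simulate_home_centres()].
#' @param n_per_individual fixes per individual.
#' @param fix_interval_hours spacing of the underlying fix schedule.
#' @param window date range (local time) the schedule spans.
#' @param edge_taper radial Gaussian taper of within-range use, as a
#'   fraction of the disc radius (`s = edge_taper * radius`); real
#'   utilization distributions decay toward the range edge rather than
#'   dropping to zero, and a hard edge would put kernel-estimated isopleth
#'   area over terrain the animal never uses. `0` disables the taper
#'   (uniform-in-disc null).
#' @param seed integer seed.
#' @return telemetry `data.frame` (`animal_id, timestamp, x, y`) with the
#'   generator's standardization constants in attribute `"standardization"`.
#' @export
simulate_telemetry <- function(rasters, gamma, centres,
                               n_per_individual = 400,
                               fix_interval_hours = 2,
                               window = c("2012-06-15", "2012-09-15"),
                               edge_taper = 0, seed = NULL) {
  local_seed(seed)
  schedule <- seq(as.POSIXct(paste(window[1], "00:00:00"), tz = "UTC"),
                  as.POSIXct(paste(window[2], "23:59:59"), tz = "UTC"),
                  by = fix_interval_hours * 3600)
  if (n_per_individual > length(schedule))
    stop("fix schedule has fewer slots than requested fixes; shorten the interval")
  slot <- unique(round(seq(1, length(schedule),
                           length.out = n_per_individual)))
  ids <- rownames(gamma)
  cells <- lapply(seq_along(ids), function(i) {
    ci <- centres[centres$individual_id == ids[i], ]
    disc_cells(rasters, ci$cx, ci$cy, ci$radius)
  })
  constants <- disc_standardization(cells)
  terms <- c("de", "ml", "wf", "de:ml", "de:wf")
  rows <- lapply(seq_along(ids), function(i) {
    ci <- centres[centres$individual_id == ids[i], ]
    Xc <- rsf_design_matrix(apply_standardization(cells[[i]]$cov, constants),
                            terms)
    eta_max <- max(drop(Xc %*% gamma[i, ]))
    pts <- matrix(NA_real_, 0, 2)
    tried <- 0L
    while (nrow(pts) < n_per_individual) {
      m <- max(4L * (n_per_individual - nrow(pts)), 256L)
      r <- ci$radius * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      px <- ci$cx + r * cos(th); py <- ci$cy + r * sin(th)
      cov <- apply_standardization(
        extract_covariates(px, py, rasters$de, rasters$lion, rasters$wolf),
        constants)
      eta <- drop(rsf_design_matrix(cov, terms) %*% gamma[i, ])
      if (edge_taper > 0)
        eta <- eta - 0.5 * (r / (edge_taper * ci$radius))^2
      keep <- log(stats::runif(m)) < eta - eta_max
      pts <- rbind(pts, cbind(px[keep], py[keep]))
      tried <- tried + m
      if (tried > 1e4 && nrow(pts) / tried < 1e-4)
        stop("rejection acceptance rate below 1e-4; use smaller coefficients")
    }
    data.frame(animal_id = ids[i], timestamp = schedule[slot],
               x = pts[seq_len(n_per_individual), 1],
               y = pts[seq_len(n_per_individual), 2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "standardization") <- constants
  out
}

#' Simulate a used-available design table directly
#'
#' The design-level counterpart of [simulate_telemetry()]: used rows are
#' raster cells inside each individual's disc sampled with probability
#' proportional to `exp(gamma_i . x)` (jittered within the cell), available
#' rows are uniform cells. Used by parameter-recovery checks where the
#' home-range estimation stage is not under test.
#'
#' @inheritParams simulate_telemetry
#' @param n_used,n_avail rows per individual.
#' @param weight_available available-row weight.
#' @return used-available `data.frame` with covariates already on the
#'   generator's standardized scale (constants in the `"standardization"`
#'   attribute), ready for [fit_hierarchical_rsf()].
#' @export
simulate_used_available <- function(rasters, gamma, centres, n_used = 300,
                                    n_avail = 10 * n_used,
                                    weight_available = 1000, seed = NULL) {
  local_seed(seed)
  ids <- rownames(gamma)
  cells <- lapply(seq_along(ids), function(i) {
    ci <- centres[centres$individual_id == ids[i], ]
    disc_cells(rasters, ci$cx, ci$cy, ci$radius)
  })
  constants <- disc_standardization(cells)
  terms <- c("de", "ml", "wf", "de:ml", "de:wf")
  cs <- rasters$de$cell_size
  rows <- lapply(seq_along(ids), function(i) {
    dc <- cells[[i]]
    cov_std <- apply_standardization(dc$cov, constants)
    eta <- drop(rsf_design_matrix(cov_std, terms) %*% gamma[i, ])
    pu <- sample.int(length(eta), n_used, replace = TRUE,
                     prob = exp(eta - max(eta)))
    pa <- sample.int(length(eta), n_avail, replace = TRUE)
    k <- c(pu, pa)
    jx <- stats::runif(length(k), -0.499, 0.499) * cs
    jy <- stats::runif(length(k), -0.499, 0.499) * cs
    data.frame(individual_id = ids[i], order = "third",
               used = rep(c(1L, 0L), c(n_used, n_avail)),
               weight = rep(c(1, weight_available), c(n_used, n_avail)),
               cov_std[k, , drop = FALSE],
               x = dc$x[k] + jx, y = dc$y[k] + jy)
  })
  out <- new_ua_table(do.call(rbind, rows), seed)
  attr(out, "standardization") <- constants
  out
}

#' Simulate fall body fat and pregnancy from trade-off metrics
#'
#' Body fat follows the Gaussian NCE model truncated to the plausible
#' [0, 30] percent range; pregnancy follows the Bernoulli-logit model.
#' Defaults are calibrated so that, with zero trade-off effects and a 0.48
#' lactation rate, median body fat is about 7.5 percent (lactating animals
#' about 2.9 points leaner) and the pregnancy rate about 0.76.
#'
#' @param tradeoff data.frame with `individual_id` and trade-off columns
#'   `ml` and/or `wf`, or `NULL` for `n` animals with zero trade-offs.
#' @param n number of animals when `tradeoff` is `NULL`.
#' @param predator which trade-off column drives the NCE truth.
#' @param bodyfat list: `alpha`, `pred`, `lact`, `pred_lact`, `sd`.
#' @param pregnancy list: `alpha` (logit scale), `pred`, `lact`, `pred_lact`.
#' @param lactation_prob probability an animal is lactating.
#' @param seed integer seed.
#' @return trade-off/demography `data.frame`
#'   (`individual_id, ml, wf, ifbf, preg, lact`).
#' @export
simulate_demography <- function(tradeoff = NULL, n = 27,
                                predator = c("ml", "wf"),
                                bodyfat = list(alpha = 8.88, pred = 0,
                                               lact = -2.89, pred_lact = 0,
                                               sd = 2.5),
                                pregnancy = list(alpha = logit(0.76),
                                                 pred = 0, lact = 0,
                                                 pred_lact = 0),
                                lactation_prob = 0.48, seed = NULL) {
  predator <- match.arg(predator)
  local_seed(seed)
  if (is.null(tradeoff)) {
    tradeoff <- data.frame(individual_id = sprintf("elk%02d", seq_len(n)),
                           ml = 0, wf = 0)
  }
  n <- nrow(tradeoff)
  if (!all(c("ml", "wf") %in% names(tradeoff))) {
    for (cc in setdiff(c("ml", "wf"), names(tradeoff))) tradeoff[[cc]] <- 0
  }
  tv <- tradeoff[[predator]]
  lact <- stats::rbinom(n, 1, lactation_prob)
  mu <- bodyfat$alpha + bodyfat$pred * tv + bodyfat$lact * lact +
    bodyfat$pred_lact * tv * lact
  ifbf <- pmin(pmax(mu + stats::rnorm(n, 0, bodyfat$sd), 0), 30)
  eta <- pregnancy$alpha + pregnancy$pred * tv + pregnancy$lact * lact +
    pregnancy$pred_lact * tv * lact
  preg <- stats::rbinom(n, 1, expit(eta))
  data.frame(individual_id = tradeoff$individual_id,
             ml = tradeoff$ml, wf = tradeoff$wf,
             ifbf = ifbf, preg = preg, lact = lact)
}

#' Trade-off statistics from true generator coefficients
#'
#' Evaluates the same exponential-difference metric as [compute_tradeoff()]
#' but from the generator's true individual coefficients; used as ground
#' truth in recovery checks.
#'
#' @param gamma coefficient matrix from [draw_individual_coefficients()].
#' @param table standardized design table supplying the quantiles.
#' @inheritParams compute_tradeoff
#' @return data.frame `individual_id, tradeoff`.
#' @export
true_tradeoff <- function(gamma, table, predator = c("ml", "wf"),
                          de_q = 0.95, hi_q = 0.95, lo_q = 0.05, at = NULL) {
  predator <- match.arg(predator)
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
  X <- rsf_design_matrix(nd, c("de", "ml", "wf", "de:ml", "de:wf"))
  X[, "intercept"] <- 0
  om <- exp(X %*% t(gamma))
  data.frame(individual_id = rownames(gamma),
             tradeoff = om[1, ] - om[2, ], row.names = NULL)
}

#' Simulate a complete synthetic study
#'
#' Landscapes, heterogeneous individuals, telemetry and demography in one
#' call, with the generative truth attached for recovery tests.
#'
#' @param n_individuals number of animals.
#' @param n_fixes GPS fixes per animal.
#' @param beta,sigma,sigma_intercept passed to
#'   [draw_individual_coefficients()].
#' @param landscape list of arguments for [generate_landscapes()].
#' @param hr_radius disc home-range radius (m).
#' @param seed master seed; stage seeds are derived from it.
#' @return list with `rasters`, `telemetry`, `demography`, `centres` and
#'   `truth` (`beta`, `sigma`, `gamma`, seeds).
#' @export
simulate_study <- function(n_individuals = 40, n_fixes = 400,
                           beta = c(intercept = 0, de = 0.2, ml = -0.1,
                                    wf = 0.3, "de:ml" = -0.1, "de:wf" = 0.03),
                           sigma = c(de = 0.15, ml = 0.15, wf = 0.15,
                                     "de:ml" = 0.15, "de:wf" = 0.15),
                           sigma_intercept = 0.5,
                           landscape = list(), hr_radius = 3000,
                           seed = 1) {
  seeds <- derive_seeds(seed, 5, salt = 11L)
  rasters <- do.call(generate_landscapes,
                     utils::modifyList(list(seed = seeds[[1]]), landscape))
  gamma <- draw_individual_coefficients(n_individuals, beta, sigma,
                                        sigma_intercept, seed = seeds[[2]])
  centres <- simulate_home_centres(n_individuals, rasters, radius = hr_radius,
                                   seed = seeds[[3]])
  telemetry <- simulate_telemetry(rasters, gamma, centres,
                                  n_per_individual = n_fixes,
                                  seed = seeds[[4]])
  demography <- simulate_demography(n = n_individuals, seed = seeds[[5]])
  demography$individual_id <- rownames(gamma)
  list(rasters = rasters, telemetry = telemetry, demography = demography,
       centres = centres,
       truth = list(beta = beta, sigma = sigma,
                    sigma_intercept = sigma_intercept, gamma = gamma,
                    seed = seed, stage_seeds = unlist(seeds)))
}
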
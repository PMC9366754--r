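# Used-available design tables for second- and third-order selection.
#
# Second order contrasts each individual's home range (used: uniform samples
# inside it) against the population summer range (available). Third order
# contrasts season- and time-filtered GPS fixes (used) against uniform
# samples from the individual's home range (available, at a fixed ratio).
# Available rows carry a large likelihood weight so the weighted logistic
# fit approximates an inhomogeneous point-process likelihood.

ua_columns <- c("individual_id", "order", "used", "weight", "de", "ml", "wf")

new_ua_table <- function(rows, seed = NULL) {
  rows <- rows[, c(ua_columns, intersect(c("x", "y"), names(rows)))]
  rownames(rows) <- NULL
  attr(rows, "seed") <- seed
  rows
}

#' Build the second-order used-available table
#'
#' For every individual, `n_used` points are drawn uniformly inside the
#' individual's summer home range (the "used" sample representing home-range
#' placement) and `n_avail` points uniformly inside the corresponding
#' population-level summer range (the "available" sample). Covariates are
#' extracted at every point.
#'
#' @param individual_hrs named list of [home_range()] objects, one per
#'   individual (animal-year).
#' @param population_hr a [home_range()], or a named list of them together
#'   with `population_of` mapping individual id to population name.
#' @param rasters list with elements `de`, `lion`, `wolf`
#'   ([raster_surface()]).
#' @param n_used,n_avail points per individual (defaults 500 and 1000).
#' @param weight_available likelihood weight given to available rows
#'   (used rows have weight 1).
#' @param population_of optional named character vector, individual id ->
#'   name in `population_hr`.
#' @param seed integer seed; the table is reproducible given the seed.
#' @return used-available `data.frame` with columns
#'   `individual_id, order, used, weight, de, ml, wf` (unstandardized).
#' @export
build_second_order_table <- function(individual_hrs, population_hr, rasters,
                                     n_used = 500, n_avail = 1000,
                                     weight_available = 1000,
                                     population_of = NULL, seed = NULL) {
  ids <- names(individual_hrs)
  if (is.null(ids)) stop("individual_hrs must be a named list")
  seeds <- derive_seeds(seed, length(ids), salt = 2L)
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    pop <- if (inherits(population_hr, "home_range")) population_hr
           else population_hr[[population_of[[id]]]]
    s <- seeds[[i]]
    pu <- sample_uniform_in_polygon(individual_hrs[[id]], n_used,
                                    seed = if (is.null(s)) NULL else s)
    pa <- sample_uniform_in_polygon(pop, n_avail,
                                    seed = if (is.null(s)) NULL else s + 1)
    xy <- rbind(pu, pa)
    cov <- extract_covariates(xy$x, xy$y, rasters$de, rasters$lion,
                              rasters$wolf)
    data.frame(individual_id = id, order = "second",
               used = rep(c(1L, 0L), c(n_used, n_avail)),
               weight = rep(c(1, weight_available), c(n_used, n_avail)),
               cov, x = xy$x, y = xy$y)
  })
  new_ua_table(do.call(rbind, rows), seed)
}

#' Build the third-order used-available table
#'
#' Used rows are the (already season/time filtered) GPS fixes of each
#' individual; available rows are uniform samples from that individual's
#' home range at `ratio` available per used location.
#'
#' @param used filtered telemetry `data.frame`
#'   (see [filter_foraging_locations()]).
#' @param individual_hrs named list of [home_range()] objects.
#' @param rasters list with elements `de`, `lion`, `wolf`.
#' @param ratio available locations per used location (default 10).
#' @param weight_available likelihood weight of available rows.
#' @param seed integer seed.
#' @return used-available `data.frame` (unstandardized). Individuals with no
#'   used rows are dropped with a warning.
#' @export
build_third_order_table <- function(used, individual_hrs, rasters,
                                    ratio = 10, weight_available = 1000,
                                    seed = NULL) {
  ids <- names(individual_hrs)
  counts <- table(factor(used$animal_id, levels = ids))
  empty <- ids[counts == 0]
  if (length(empty)) {
    warning("excluding individuals with zero used locations: ",
            paste(empty, collapse = ", "))
    ids <- setdiff(ids, empty)
  }
  unknown <- setdiff(unique(used$animal_id), names(individual_hrs))
  if (length(unknown))
    stop("no home range for individual(s): ", paste(unknown, collapse = ", "))
  seeds <- derive_seeds(seed, length(ids), salt = 3L)
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    pts <- used[used$animal_id == id, , drop = FALSE]
    na <- ratio * nrow(pts)
    pa <- sample_uniform_in_polygon(individual_hrs[[id]], na,
                                    seed = seeds[[i]])
    xy <- rbind(pts[, c("x", "y")], pa)
    cov <- extract_covariates(xy$x, xy$y, rasters$de, rasters$lion,
                              rasters$wolf)
    data.frame(individual_id = id, order = "third",
               used = rep(c(1L, 0L), c(nrow(pts), na)),
               weight = rep(c(1, weight_available), c(nrow(pts), na)),
               cov, x = xy$x, y = xy$y)
  })
  new_ua_table(do.call(rbind, rows), seed)
}

#' Centre and scale the covariate columns of a design table
#'
#' Each covariate column is centred by its mean and divided by one sample
#' standard deviation (n - 1 denominator), computed over the pooled used and
#' available rows of the table. The constants are stored in the
#' `"standardization"` attribute so predictions and trade-off quantiles can
#' be mapped back to natural units.
#'
#' A warning reports any pairwise correlation above 0.50, the conventional
#' collinearity screen for selection covariates.
#'
#' @param table used-available `data.frame`.
#' @param cols covariate columns to standardize.
#' @param constants optional precomputed constants (a named list of
#'   `c(mean, sd)`) to apply instead of the table's own.
#' @return the table with standardized covariates and attribute
#'   `"standardization"`.
#' @export
standardize_covariates <- function(table, cols = c("de", "ml", "wf"),
                                   constants = NULL) {
  if (is.null(constants)) {
    constants <- lapply(table[cols], function(v) {
      if (any(!is.finite(v))) stop("non-finite covariate values")
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0)
        stop("degenerate covariate: constant column cannot be standardized")
      c(mean = mean(v), sd = s)
    })
  }
  for (cc in cols)
    table[[cc]] <- (table[[cc]] - constants[[cc]]["mean"]) /
      constants[[cc]]["sd"]
  cm <- stats::cor(as.matrix(table[cols]))
  hi <- which(abs(cm) > 0.5 & upper.tri(cm), arr.ind = TRUE)
  if (nrow(hi)) {
    warning("covariate correlation exceeds 0.50: ",
            paste(sprintf("%s-%s r=%.2f", cols[hi[, 1]], cols[hi[, 2]],
                          cm[hi]), collapse = "; "))
  }
  attr(table, "standardization") <- constants
  attr(table, "correlations") <- cm
  table
}

#' Undo covariate standardization
#' @param table a table produced by [standardize_covariates()].
#' @return the table on the natural covariate scale.
#' @export
destandardize_covariates <- function(table) {
  constants <- attr(table, "standardization")
  if (is.null(constants)) stop("table carries no standardization constants")
  for (cc in names(constants))
    table[[cc]] <- table[[cc]] * constants[[cc]]["sd"] + constants[[cc]]["mean"]
  attr(table, "standardization") <- NULL
  table
}

#' Covariate correlation diagnostics
#'
#' Pairwise correlations (and squared correlations) between the covariate
#' columns of a design table; the forage-predator squared correlations are
#' the standard diagnostic for whether a forage-risk trade-off is even
#' possible on the landscape.
#'
#' @param table used-available `data.frame`.
#' @param cols covariate columns.
#' @return list with elements `r` (correlation matrix) and `r2`.
#' @export
covariate_correlations <- function(table, cols = c("de", "ml", "wf")) {
  r <- stats::cor(as.matrix(table[cols]))
  list(r = r, r2 = r^2)
}

#' Write a used-available table to CSV (with JSON sidecar)
#'
#' Values are written at full double precision so the table round-trips
#' losslessly; standardization constants and the seed go to `<path>.json`.
#'
#' @param table used-available `data.frame`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ua_table <- function(table, path) {
  d <- table[, ua_columns]
  for (cc in c("weight", "de", "ml", "wf"))
    d[[cc]] <- sprintf("%.17g", d[[cc]])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  side <- list(seed = attr(table, "seed"),
               standardization = lapply(attr(table, "standardization"),
                                        as.list))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a used-available table written by [write_ua_table()]
#' @param path CSV path.
#' @return used-available `data.frame` with restored attributes.
#' @export
read_ua_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(individual_id = "character",
                                      weight = "numeric"))
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$standardization)) {
      attr(d, "standardization") <- lapply(side$standardization, function(s)
        c(mean = as.numeric(s[["mean"]]), sd = as.numeric(s[["sd"]])))
    }
    attr(d, "seed") <- side$seed
  }
  d
}
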
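# Fivefold by-individual cross-validation in the style of Boyce et al.:
# withheld predictions are cut into ordinal habitat-suitability bins at
# percentiles of the withheld *available* predictions, and the frequency of
# withheld *used* locations per bin is tested against the bin ranks with a
# Spearman rank correlation.

#' Randomly assign individuals to folds
#'
#' @param ids character vector of individual ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return named integer vector, id -> fold; fold sizes differ by at most 1.
#' @export
assign_folds <- function(ids, k = 5, seed = NULL) {
  ids <- unique(as.character(ids))
  if (length(ids) < k) stop("fewer individuals than folds")
  local_seed(seed)
  fold <- rep(seq_len(k), length.out = length(ids))[sample.int(length(ids))]
  names(fold) <- ids
  fold
}

#' Spearman rank correlation with an exact small-sample test
#'
#' Ties get midranks. For `n <= 8` the two-sided p-value is computed by full
#' enumeration of all permutations of one margin; larger samples use the
#' t approximation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rs` and `p`.
#' @export
spearman_rank <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal lengths >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero-variance input: ranks are constant")
  rs <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2))
    r_all <- apply(perms, 1, function(pp) {
      ryp <- ry[pp] - mean(ry)
      sum(rxc * ryp) / (denom * sqrt(sum(ryp^2)))
    })
    p <- mean(abs(r_all) >= abs(rs) - 1e-12)
  } else {
    tt <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rs = rs, p = min(p, 1))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Bin withheld predictions into habitat ranks and tally used locations
#'
#' Cutoffs are the `(1:(n_bins-1))/n_bins` percentiles of the withheld
#' available predictions; used predictions are counted per bin. Empty bins
#' keep count zero.
#'
#' @param pred_used,pred_avail predicted relative use for withheld used and
#'   available rows.
#' @param n_bins number of ordinal bins (default 5).
#' @return list with `counts` (length `n_bins`), `cutoffs`, and
#'   `degenerate` (TRUE when all available predictions are equal).
#' @export
habitat_rank_counts <- function(pred_used, pred_avail, n_bins = 5) {
  cuts <- stats::quantile(pred_avail, seq_len(n_bins - 1) / n_bins,
                          names = FALSE)
  degenerate <- length(unique(pred_avail)) == 1 ||
    any(duplicated(cuts))
  bin <- findInterval(pred_used, cuts, left.open = TRUE) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  list(counts = counts, cutoffs = cuts, degenerate = degenerate)
}

#' Fivefold Boyce-style cross-validation of an RSF
#'
#' Individuals are partitioned into folds; for each fold the model is refit
#' on the retained individuals, withheld rows are predicted at the
#' population level, and withheld used locations are tallied across habitat
#' rank bins cut at percentiles of the withheld available predictions. Fit
#' quality is the Spearman correlation between bin counts and ranks 1..n_bins.
#'
#' @param table standardized used-available table.
#' @param spec an [rsf_model_spec()].
#' @param folds a fold assignment from [assign_folds()], or `NULL` to draw
#'   one with `k = 5` and `seed`.
#' @param n_bins number of habitat rank bins.
#' @param method estimation mode for the refits (`"map"` is the fast mode).
#' @param area_adjusted divide bin counts by the withheld available count
#'   per bin (a Boyce-ratio variant) before the rank test.
#' @param seed integer seed (fold draw only).
#' @param ... further arguments to [fit_hierarchical_rsf()].
#' @return list with per-fold results (`rs`, `p`, `counts`, `cutoffs`,
#'   `degenerate`) and `mean_rs`.
#' @export
boyce_cross_validate <- function(table, spec = rsf_model_spec(), folds = NULL,
                                 n_bins = 5, method = "map",
                                 area_adjusted = FALSE, seed = NULL, ...) {
  ids <- unique(as.character(table$individual_id))
  if (is.null(folds)) folds <- assign_folds(ids, k = 5, seed = seed)
  k <- max(folds)
  per_fold <- lapply(seq_len(k), function(f) {
    held <- names(folds)[folds == f]
    train <- table[!(table$individual_id %in% held), , drop = FALSE]
    test <- table[table$individual_id %in% held, , drop = FALSE]
    if (!any(test$used == 1) || !any(test$used == 0))
      stop("withheld fold ", f, " lacks used or available rows")
    fit <- fit_hierarchical_rsf(train, spec, method = method, ...)
    pred <- predict_relative_use(fit, test, level = "population")
    hb <- habitat_rank_counts(pred[test$used == 1], pred[test$used == 0],
                              n_bins)
    stat <- hb$counts
    if (area_adjusted) {
      avail_bin <- habitat_rank_counts(pred[test$used == 0],
                                       pred[test$used == 0], n_bins)$counts
      stat <- stat / pmax(avail_bin, 1)
    }
    sp <- spearman_rank(seq_len(n_bins), stat)
    c(hb, list(rs = sp$rs, p = sp$p, n_used = sum(test$used == 1),
               individuals = held))
  })
  if (any(vapply(per_fold, `[[`, TRUE, "degenerate")))
    warning("degenerate predictions (tied bin cutoffs) in at least one fold")
  list(folds = per_fold,
       mean_rs = mean(vapply(per_fold, `[[`, 0, "rs")),
       fold_assignment = folds, n_bins = n_bins)
}

#' Write a cross-validation report as JSON
#' @param cv result of [boyce_cross_validate()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  rep <- list(mean_rs = cv$mean_rs, n_bins = cv$n_bins,
              folds = lapply(cv$folds, function(f)
                f[c("rs", "p", "counts", "cutoffs", "n_used")]))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
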
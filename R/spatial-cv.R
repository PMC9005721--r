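# Spatial-block cross-validation: contiguous geographic blocks, not points,
# are assigned to folds, so test data are spatially separated from training
# data and the evaluation is not inflated by spatial autocorrelation.

#' Build spatially blocked cross-validation folds
#'
#' Tiles the points' bounding box with square blocks of edge \code{block_km}
#' and, for each repeat, assigns every block to one of \code{k} folds
#' uniformly at random. If an assignment leaves a fold empty, one block is
#' reassigned from the fold currently holding the most blocks, so all
#' \code{k} folds are populated.
#'
#' @param points Data frame with \code{lon}, \code{lat}.
#' @param block_km Block edge length, km (default 100).
#' @param k Number of folds (default 13).
#' @param repeats Independent random splittings (default 20).
#' @param seed Integer seed.
#' @return List of \code{fold_assignment} objects (one per repeat), each
#'   with \code{fold} (integer per point), \code{block} (block key per
#'   point), \code{k}, \code{block_km}, \code{repeat_id}.
#' @export
make_folds <- function(points, block_km = 100, k = 13, repeats = 20,
                       seed = 1) {
  stopifnot(k >= 2, repeats >= 1)
  tiling <- tiling_for_points(points, block_km)
  keys <- block_index(tiling, points$lon, points$lat)$key
  blocks <- unique(keys)
  if (length(blocks) < k)
    stop(sprintf(paste0("only %d distinct spatial blocks for %d folds; ",
                        "use a smaller block_km than %g"),
                 length(blocks), k, block_km))
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    fold_of_block <- sample.int(k, length(blocks), replace = TRUE)
    repeat {
      counts <- tabulate(fold_of_block, nbins = k)
      empty <- which(counts == 0L)
      if (!length(empty)) break
      donor <- which.max(counts)
      move <- which(fold_of_block == donor)[1L]
      fold_of_block[move] <- empty[1L]
    }
    structure(list(fold = fold_of_block[match(keys, blocks)],
                   block = keys, k = k, block_km = block_km,
                   repeat_id = r, tiling = tiling),
              class = "fold_assignment")
  })
}

#' Non-spatial (random) fold assignment
#'
#' Points are assigned to folds individually at random, ignoring geography;
#' the conventional CV baseline that spatial blocking is compared against.
#'
#' @param n Number of points.
#' @param k,repeats,seed As in [make_folds()].
#' @return List of \code{fold_assignment} objects (block = point index).
#' @export
make_random_folds <- function(n, k = 13, repeats = 20, seed = 1) {
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    fold <- sample(rep_len(seq_len(k), n))
    structure(list(fold = fold, block = as.character(seq_len(n)), k = k,
                   block_km = NA_real_, repeat_id = r, tiling = NULL),
              class = "fold_assignment")
  })
}

#' ROC-AUC for binary labels
#'
#' Threshold-free evaluation: the probability that a random presence scores
#' above a random absence, ties counted half. Computed by the rank
#' (Mann-Whitney) formula, \code{AUC = (concordant + 0.5 * tied) /
#' (n_pos * n_neg)}.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary vector (0/1), both classes present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop(errorCondition("AUC undefined: only one class present",
                        class = "undefined_auc"))
  r <- rank(scores)            # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-validated random-forest evaluation
#'
#' For every repeat and fold: fit a random forest on the training blocks,
#' score the test blocks with class-probability votes, and compute ROC-AUC.
#' Folds whose test set contains a single class have no defined AUC and are
#' recorded as skipped (never imputed); folds whose training set is
#' single-class are likewise skipped.
#'
#' @param features Covariate data frame.
#' @param labels Binary labels (0/1).
#' @param assignments List of \code{fold_assignment}, e.g. from
#'   [make_folds()].
#' @param rf_params randomForest overrides.
#' @param seed Integer seed.
#' @return Object of class \code{cv_report}: \code{folds} (data frame with
#'   one row per repeat x fold), \code{auc_mean}, \code{auc_sd} (unweighted
#'   over defined folds), \code{n_skipped}.
#' @export
cross_validate <- function(features, labels, assignments, rf_params = list(),
                           seed = 1) {
  stopifnot(length(assignments) >= 1)
  rows <- list()
  for (a in assignments) {
    stopifnot(inherits(a, "fold_assignment"),
              length(a$fold) == length(labels))
    for (f in seq_len(a$k)) {
      test <- a$fold == f
      auc <- NA_real_
      skipped <- NA_character_
      if (length(unique(labels[!test])) < 2L) {
        skipped <- "single-class training fold"
      } else if (length(unique(labels[test])) < 2L) {
        skipped <- "single-class test fold"
      } else {
        rf <- rf_fit(features[!test, , drop = FALSE], labels[!test],
                     rf_params, seed = seed + 1000L * a$repeat_id + f)
        auc <- roc_auc(rf_prob(rf, features[test, , drop = FALSE]),
                       labels[test])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = a$repeat_id, fold = f, auc = auc,
        n_test_presence = sum(labels[test] == 1L),
        n_test_absence = sum(labels[test] == 0L),
        skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  folds <- do.call(rbind, rows)
  ok <- !is.na(folds$auc)
  structure(list(folds = folds,
                 auc_mean = mean(folds$auc[ok]),
                 auc_sd = stats::sd(folds$auc[ok]),
                 n_skipped = sum(!ok)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: AUC %.3f +/- %.3f over %d defined folds (%d skipped)\n",
              x$auc_mean, x$auc_sd, sum(!is.na(x$folds$auc)), x$n_skipped))
  invisible(x)
}
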
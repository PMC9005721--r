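# Two-stage covariate selection: Pearson correlation grouping at
# |r| >= 0.8, then random-forest importance (mean decrease in Gini impurity
# and permutation mean decrease in accuracy) with sequential resolution of
# correlated groups by candidate-model comparison.

#' Correlation groups of covariates
#'
#' Computes the pairwise Pearson correlation matrix over training rows and
#' partitions the variables into the connected components of the graph whose
#' edges join pairs with \code{|r| >= threshold}. Mutually exclusive sets of
#' redundant covariates fall out as multi-member groups.
#'
#' @param features Data frame of covariates (>= 2 rows, finite values).
#' @param threshold Absolute correlation threshold (default 0.8).
#' @return Object of class \code{correlation_groups}: \code{matrix},
#'   \code{groups} (list of character vectors), \code{threshold},
#'   \code{excluded} (zero-variance columns, flagged with a warning and left
#'   out of the grouping).
#' @export
correlation_groups <- function(features, threshold = 0.8) {
  stopifnot(nrow(features) >= 2)
  m <- as.matrix(features)
  if (any(!is.finite(m))) stop("features contain non-finite values")
  vars <- colnames(m)
  sds <- apply(m, 2, stats::sd)
  excluded <- vars[sds == 0]
  if (length(excluded))
    warning("zero-variance column(s) excluded from selection: ",
            paste(excluded, collapse = ", "))
  keep <- setdiff(vars, excluded)
  cm <- matrix(NA_real_, length(vars), length(vars),
               dimnames = list(vars, vars))
  if (length(keep) >= 1) cm[keep, keep] <- stats::cor(m[, keep, drop = FALSE])
  diag(cm) <- 1
  # connected components over |r| >= threshold edges (simple BFS; the
  # variable count is small)
  adj <- !is.na(cm) & abs(cm) >= threshold
  diag(adj) <- FALSE
  unvisited <- keep
  groups <- list()
  while (length(unvisited)) {
    comp <- unvisited[1]
    frontier <- comp
    while (length(frontier)) {
      nb <- setdiff(vars[apply(adj[frontier, , drop = FALSE], 2, any)], comp)
      nb <- intersect(nb, unvisited)
      comp <- c(comp, nb)
      frontier <- nb
    }
    groups[[length(groups) + 1L]] <- comp
    unvisited <- setdiff(unvisited, comp)
  }
  structure(list(matrix = cm, groups = groups, threshold = threshold,
                 excluded = excluded),
            class = "correlation_groups")
}

#' @export
print.correlation_groups <- function(x, ...) {
  multi <- Filter(function(g) length(g) > 1, x$groups)
  cat(sprintf("correlation_groups: %d variables, %d groups (|r| >= %g), %d multi-member\n",
              nrow(x$matrix), length(x$groups), x$threshold, length(multi)))
  for (g in multi) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

# Out-of-bag majority-vote accuracy from per-tree predictions.
oob_accuracy <- function(individual, oob, labels) {
  votes1 <- rowSums((individual == "1") & oob)
  total <- rowSums(oob)
  use <- total > 0
  pred <- votes1[use] / total[use] > 0.5
  mean(pred == (labels[use] == 1))
}

#' Random-forest variable importance (MDG and MDA)
#'
#' Fits a random-forest classifier and reports, per variable: MDG, the total
#' decrease in Gini impurity attributed to the variable across all trees
#' divided by the number of trees (taken from the fitted forest); and MDA,
#' the drop in out-of-bag majority-vote accuracy when the variable's column
#' is permuted, averaged over \code{n_permutations} independent
#' permutations. MDA of a pure-noise variable fluctuates around zero and may
#' be slightly negative.
#'
#' @param features Covariate data frame.
#' @param labels Binary vector (0/1); both classes must be present.
#' @param rf_params List of randomForest overrides (\code{ntree},
#'   \code{mtry}, ...).
#' @param n_permutations Permutation repeats for MDA (default 10).
#' @param seed Integer seed.
#' @return Object of class \code{importance_table}: data frame with columns
#'   \code{variable}, \code{mdg}, \code{mda}, \code{rank_mdg},
#'   \code{rank_mda} (rank 1 = most important).
#' @export
rf_importance <- function(features, labels, rf_params = list(),
                          n_permutations = 10, seed = 1) {
  rf <- rf_fit(features, labels, rf_params, seed = seed,
               importance = TRUE, keep.inbag = TRUE, keep.forest = TRUE)
  mdg <- randomForest::importance(rf, type = 2)[, 1]
  oob <- rf$inbag == 0
  ind0 <- stats::predict(rf, features, predict.all = TRUE)$individual
  acc0 <- oob_accuracy(ind0, oob, labels)
  p <- ncol(features)
  mda <- numeric(p)
  for (v in seq_len(p)) {
    drop_v <- 0
    for (r in seq_len(n_permutations)) {
      xp <- features
      xp[[v]] <- xp[[v]][sample.int(nrow(xp))]
      indp <- stats::predict(rf, xp, predict.all = TRUE)$individual
      drop_v <- drop_v + (acc0 - oob_accuracy(indp, oob, labels))
    }
    mda[v] <- drop_v / n_permutations
  }
  out <- data.frame(variable = colnames(features), mdg = unname(mdg),
                    mda = mda,
                    rank_mdg = rank(-mdg, ties.method = "first"),
                    rank_mda = rank(-mda, ties.method = "first"),
                    stringsAsFactors = FALSE)
  class(out) <- c("importance_table", "data.frame")
  attr(out, "oob_accuracy") <- acc0
  out
}

# Spatial (or random) CV AUC of a candidate variable set; used to arbitrate
# between near-equally important members of a correlation group.
candidate_auc <- function(features, labels, vars, coords, tiebreak, seed) {
  folds <- if (!is.null(coords))
    make_folds(coords, block_km = tiebreak$block_km, k = tiebreak$k,
               repeats = tiebreak$repeats, seed = seed)
  else
    make_random_folds(length(labels), k = tiebreak$k,
                      repeats = tiebreak$repeats, seed = seed)
  rep <- cross_validate(features[, vars, drop = FALSE], labels, folds,
                        rf_params = tiebreak$rf_params, seed = seed + 1L)
  rep$auc_mean
}

#' Two-stage covariate selection
#'
#' Implements the selection workflow: (1) correlation grouping at
#' \code{|r| >= threshold}; (2) MDG/MDA importance of all variables;
#' (3) singleton variables are kept when they rank in the top half by MDG
#' \emph{or} by MDA; (4) each multi-member group is resolved sequentially:
#' the members with the best MDG rank and the best MDA rank are
#' shortlisted; if they coincide that member is kept, otherwise one
#' candidate model per shortlist member is fitted (the group's other
#' members excluded, the current kept set included) and the member whose
#' model attains the higher cross-validated AUC wins. Every decision is
#' recorded in an audit log.
#'
#' @param features Covariate data frame.
#' @param labels Binary labels (0/1).
#' @param coords Optional data frame of point coordinates (\code{lon},
#'   \code{lat}); when given, candidate models are compared by
#'   spatial-block CV AUC, otherwise by random-fold CV AUC.
#' @param threshold Correlation threshold (default 0.8).
#' @param rf_params randomForest overrides for the importance forest.
#' @param n_permutations MDA permutation repeats.
#' @param tiebreak List controlling candidate-model CV: \code{k},
#'   \code{repeats}, \code{block_km}, \code{rf_params}.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @return Object of class \code{feature_selection}: \code{selected}
#'   (character vector ordered by MDG rank), \code{audit} (list of decision
#'   records), \code{groups}, \code{importance}.
#' @export
select_features <- function(features, labels, coords = NULL, threshold = 0.8,
                            rf_params = list(), n_permutations = 10,
                            tiebreak = list(k = 5, repeats = 1,
                                            block_km = 100,
                                            rf_params = list(ntree = 200)),
                            seed = 1) {
  cg <- correlation_groups(features, threshold)
  usable <- setdiff(colnames(features), cg$excluded)
  imp <- rf_importance(features[, usable, drop = FALSE], labels,
                       rf_params = rf_params,
                       n_permutations = n_permutations, seed = seed)
  p <- length(usable)
  half <- ceiling(p / 2)
  audit <- list()
  note <- function(...) audit[[length(audit) + 1L]] <<- list(...)
  for (v in cg$excluded)
    note(variable = v, decision = "dropped", reason = "zero variance")

  irow <- function(v) imp[imp$variable == v, ]
  selected <- character(0)

  singles <- unlist(Filter(function(g) length(g) == 1, cg$groups))
  for (v in singles) {
    r <- irow(v)
    if (r$rank_mdg <= half || r$rank_mda <= half) {
      selected <- c(selected, v)
      note(variable = v, decision = "kept",
           reason = sprintf("singleton in top half (rank MDG %d, MDA %d of %d)",
                            r$rank_mdg, r$rank_mda, p))
    } else {
      note(variable = v, decision = "dropped",
           reason = sprintf("singleton below median importance (rank MDG %d, MDA %d of %d)",
                            r$rank_mdg, r$rank_mda, p))
    }
  }

  multis <- Filter(function(g) length(g) > 1, cg$groups)
  if (length(multis)) {
    # resolve groups in order of their best member's MDG rank, for a
    # deterministic sequential search
    best_rank <- vapply(multis, function(g)
      min(vapply(g, function(v) irow(v)$rank_mdg, numeric(1))), numeric(1))
    multis <- multis[order(best_rank)]
    for (gi in seq_along(multis)) {
      g <- multis[[gi]]
      by_mdg <- g[which.min(vapply(g, function(v) irow(v)$rank_mdg, numeric(1)))]
      by_mda <- g[which.min(vapply(g, function(v) irow(v)$rank_mda, numeric(1)))]
      if (identical(by_mdg, by_mda)) {
        selected <- c(selected, by_mdg)
        note(variable = by_mdg, decision = "kept",
             reason = sprintf("best of group {%s} by both MDG and MDA",
                              paste(g, collapse = ", ")))
        for (v in setdiff(g, by_mdg))
          note(variable = v, decision = "dropped",
               reason = sprintf("correlate of %s (|r| >= %g)", by_mdg,
                                threshold))
      } else {
        aucs <- vapply(c(by_mdg, by_mda), function(cand)
          candidate_auc(features, labels, c(selected, cand), coords,
                        tiebreak, seed = seed + 100L + gi), numeric(1))
        winner <- if (aucs[2] > aucs[1]) by_mda else by_mdg
        selected <- c(selected, winner)
        note(variable = winner, decision = "kept",
             reason = sprintf(
               "group {%s}: MDG favours %s, MDA favours %s; candidate-model CV AUC %.4f vs %.4f",
               paste(g, collapse = ", "), by_mdg, by_mda, aucs[1], aucs[2]))
        for (v in setdiff(g, winner))
          note(variable = v, decision = "dropped",
               reason = sprintf("correlate of %s lost candidate-model comparison",
                                winner))
      }
    }
  }

  ord <- order(vapply(selected, function(v) irow(v)$rank_mdg, numeric(1)))
  structure(list(selected = selected[ord], audit = audit, groups = cg,
                 importance = imp, threshold = threshold, seed = seed),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("feature_selection: %d of %d variables kept (|r| >= %g grouping)\n",
              length(x$selected), nrow(x$importance) +
                length(x$groups$excluded), x$threshold))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection audit log as JSON
#'
#' @param selection A \code{feature_selection}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_audit_log <- function(selection, path) {
  stopifnot(inherits(selection, "feature_selection"))
  jsonlite::write_json(
    list(selected = selection$selected, audit = selection$audit),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
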
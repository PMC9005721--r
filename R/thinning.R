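# Spatial thinning of occurrence records: enforce a minimum nearest-neighbour
# distance while discarding as few records as possible, via repeated runs of
# a greedy max-degree removal heuristic with random tie-breaking.

#' Spatially thin a point set
#'
#' Repeatedly (for \code{iterations} runs) removes points until no two
#' survivors are closer than \code{distance_km} (haversine). Within a run,
#' while any point has a neighbour within the distance, one point is removed
#' uniformly at random among those with the maximal neighbour count; the run
#' retaining the most points wins (ties: first achieved). This is the
#' standard greedy heuristic for the underlying maximum-independent-set
#' problem on the proximity graph.
#'
#' @param points Data frame with columns \code{lon}, \code{lat}.
#' @param distance_km Minimum allowed pairwise distance, km (> 0). Pairs at
#'   exactly \code{distance_km} are allowed.
#' @param iterations Number of random restarts (default 100).
#' @param seed Integer seed; the whole restart schedule is deterministic
#'   given it.
#' @return An object of class \code{thinning_result}: list with
#'   \code{retained} (integer indices into \code{points}), \code{points}
#'   (the retained rows), \code{per_iteration_counts}, \code{distance_km},
#'   \code{iterations}, \code{seed}.
#' @export
thin_points <- function(points, distance_km, iterations = 100, seed = 1) {
  if (!is.finite(distance_km) || distance_km <= 0)
    stop("distance_km must be > 0")
  if (iterations < 1) stop("iterations must be >= 1")
  n <- nrow(points)
  res <- function(retained, counts) {
    structure(list(retained = retained,
                   points = points[retained, , drop = FALSE],
                   per_iteration_counts = counts,
                   distance_km = distance_km, iterations = iterations,
                   seed = seed),
              class = "thinning_result")
  }
  if (n == 0L) return(res(integer(0), integer(0)))
  d <- haversine_matrix(points)
  adj <- d < distance_km
  diag(adj) <- FALSE
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ]))
  deg0 <- lengths(nbr)
  if (all(deg0 == 0L))
    return(res(seq_len(n), rep(n, iterations)))

  set.seed(seed)
  best <- integer(0)
  counts_log <- integer(iterations)
  for (it in seq_len(iterations)) {
    alive <- rep(TRUE, n)
    deg <- deg0
    repeat {
      mx <- max(deg)
      if (mx == 0L) break
      cand <- which(deg == mx)
      rm <- cand[sample.int(length(cand), 1L)]
      alive[rm] <- FALSE
      hit <- nbr[[rm]]
      hit <- hit[alive[hit]]
      deg[hit] <- deg[hit] - 1L
      deg[rm] <- 0L
    }
    kept <- which(alive)
    counts_log[it] <- length(kept)
    if (length(kept) > length(best)) best <- kept
  }
  res(best, counts_log)
}

#' @export
print.thinning_result <- function(x, ...) {
  cat(sprintf("thinning_result: %d retained at >= %g km (%d iterations, seed %d)\n",
              length(x$retained), x$distance_km, x$iterations, x$seed))
  invisible(x)
}

#' Thinning-distance comparison across the full pipeline
#'
#' Runs the downstream stages (pseudo-absence assembly, spatially blocked
#' cross-validation, final fit, projection, map summary) once per candidate
#' presence set and tabulates the diagnostics used to choose a thinning
#' distance: cross-validated ROC-AUC, suitability band fractions, and the
#' spatial variability of predictions over blocks. The distance maximising
#' block variability is flagged as the suggested choice (an operational
#' stand-in for expert inspection of the maps: a model that merely echoes the
#' clustered sampling produces flat, low-variability predictions away from
#' the clusters).
#'
#' @param presence_sets Named list: thinning label -> presence data frame
#'   (e.g. \code{"0"} for unthinned, \code{"7"} for 7 km).
#' @param stack Present-climate \code{env_stack}.
#' @param truth Optional true-suitability \code{env_grid}; when supplied, the
#'   RMSE of each map against it is reported.
#' @param pa List of [pa_config()] arguments shared by all candidates;
#'   \code{n_total} defaults to each candidate's presence count (1:1).
#' @param cv List with \code{block_km}, \code{k}, \code{repeats}.
#' @param rf_params Random-forest parameters, see [fit_final_model()].
#' @param bands \code{c(low, high)} suitability report thresholds.
#' @param seed Integer seed.
#' @return List with \code{table} (one row per candidate) and
#'   \code{suggested} (label with maximal block variability), class
#'   \code{thinning_comparison}.
#' @export
compare_thinnings <- function(presence_sets, stack, truth = NULL,
                              pa = list(),
                              cv = list(block_km = 100, k = 5, repeats = 2),
                              rf_params = list(ntree = 300),
                              bands = c(0.25, 0.5), seed = 1) {
  stopifnot(length(presence_sets) >= 1, !is.null(names(presence_sets)))
  rows <- list()
  maps <- list()
  for (label in names(presence_sets)) {
    pres <- presence_sets[[label]]
    if (nrow(pres) == 0L) stop("empty presence set for distance ", label)
    r <- tryCatch({
      pa_args <- pa
      if (is.null(pa_args$n_total)) pa_args$n_total <- nrow(pres)
      if (is.null(pa_args$seed)) pa_args$seed <- seed
      cfg <- do.call(pa_config, pa_args)
      tr <- assemble_training_set(pres, cfg, stack)
      folds <- make_folds(tr$occ, block_km = cv$block_km, k = cv$k,
                          repeats = cv$repeats, seed = seed + 7)
      rep <- cross_validate(tr$features, tr$occ$label, folds,
                            rf_params = rf_params, seed = seed + 11)
      model <- fit_final_model(tr$features, tr$occ$label,
                               selected_vars = names(tr$features),
                               rf_params = rf_params, seed = seed + 13)
      map <- project_suitability(model, stack, scenario = label)
      smry <- summarize_map(map, low = bands[1], high = bands[2],
                            block_km = cv$block_km)
      maps[[label]] <- map
      data.frame(label = label, n_points = nrow(pres),
                 cv_auc_mean = rep$auc_mean, cv_auc_sd = rep$auc_sd,
                 fraction_below_low = smry$fraction_below_low,
                 fraction_above_high = smry$fraction_above_high,
                 mean_suitability = smry$mean_suitability,
                 block_variability = smry$block_variability,
                 rmse_truth = if (is.null(truth)) NA_real_
                              else map_rmse(map, truth),
                 stringsAsFactors = FALSE)
    }, error = function(e)
      stop("pipeline failed for thinning '", label, "': ",
           conditionMessage(e), call. = FALSE))
    rows[[label]] <- r
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  suggested <- tab$label[which.max(tab$block_variability)]
  structure(list(table = tab, suggested = suggested, maps = maps),
            class = "thinning_comparison")
}

#' @export
print.thinning_comparison <- function(x, ...) {
  print(x$table, digits = 3)
  cat("suggested (max block variability):", x$suggested, "\n")
  invisible(x)
}

#' RMSE between a suitability map and a reference grid
#'
#' Root-mean-square difference over cells unmasked in both; the reference is
#' typically a known true-suitability surface.
#'
#' @param map A \code{suitability_map} or \code{env_grid}.
#' @param truth Reference \code{env_grid}, same geometry.
#' @return Scalar RMSE.
#' @export
map_rmse <- function(map, truth) {
  g <- if (inherits(map, "suitability_map")) map$grid else map
  stopifnot(same_geometry(g, truth))
  d <- g$values - truth$values
  sqrt(mean(d[!is.na(d)]^2))
}
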
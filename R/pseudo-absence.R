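# Pseudo-absence generation for presence-only modelling: a combination of
# the "disk" strategy (exclusion radius around every presence) and a
# latitude-filtered "random" strategy placing absences in the far north,
# beyond the species' cold limit.

#' Pseudo-absence configuration
#'
#' @param n_total Total number of pseudo-absences. The pipeline default is
#'   one per (thinned) presence, i.e. 1:1 class balance.
#' @param disk_fraction Fraction generated by the disk strategy (default
#'   0.5); the remainder comes from the latitude-filtered random strategy.
#' @param min_dist_km Disk exclusion radius, km (default 25).
#' @param lat_threshold Random points are kept only north of this latitude,
#'   degrees (default 64, a tundra boundary).
#' @param thin_pa If \code{TRUE}, pseudo-absences are additionally thinned at
#'   \code{thin_distance_km} so they carry the same spatial footprint as the
#'   thinned presences (off by default).
#' @param thin_distance_km Thinning distance for \code{thin_pa}.
#' @param bias Optional accessibility \code{env_grid}; when supplied,
#'   disk-strategy proposals are drawn with probability proportional to it
#'   instead of uniformly, giving pseudo-absences the same sampling bias as
#'   the presences (experimental alternative mode).
#' @param seed Integer seed.
#' @return A list of class \code{pa_config}.
#' @export
pa_config <- function(n_total, disk_fraction = 0.5, min_dist_km = 25,
                      lat_threshold = 64, thin_pa = FALSE,
                      thin_distance_km = 7, bias = NULL, seed = 1) {
  stopifnot(n_total >= 1, disk_fraction >= 0, disk_fraction <= 1,
            min_dist_km > 0)
  structure(list(n_total = as.integer(n_total),
                 disk_fraction = disk_fraction, min_dist_km = min_dist_km,
                 lat_threshold = lat_threshold, thin_pa = thin_pa,
                 thin_distance_km = thin_distance_km, bias = bias,
                 seed = as.integer(seed)),
            class = "pa_config")
}

# Uniform (or bias-weighted) sample of unmasked cells, jittered within cell.
propose_points <- function(domain, n, cells, weights = NULL) {
  pick <- if (is.null(weights)) cells[sample.int(nrow(cells), n, replace = TRUE), ]
          else cells[sample.int(nrow(cells), n, replace = TRUE,
                                prob = weights), ]
  cs <- domain$cellsize
  lon_ll <- domain$xllcorner + (pick$col - 1) * cs
  lat_ll <- domain$yllcorner + (domain$nrows - pick$row) * cs
  data.frame(lon = lon_ll + stats::runif(n) * cs,
             lat = lat_ll + stats::runif(n) * cs)
}

unmasked_cells <- function(domain) {
  cc <- cell_centers(domain)
  cc[!is.na(domain$values[cbind(cc$row, cc$col)]), , drop = FALSE]
}

#' Disk-strategy pseudo-absences
#'
#' Rejection-samples points uniformly over the unmasked domain (jittered
#' within cells) and accepts those at least \code{min_dist_km} (haversine)
#' from every presence, until \code{n} are accepted.
#'
#' @param presences Data frame of presence coordinates (\code{lon},
#'   \code{lat}).
#' @param domain \code{env_grid} whose NODATA mask defines the study area
#'   (use the stack's union mask grid).
#' @param n Number of points (>= 0).
#' @param min_dist_km Exclusion radius, km.
#' @param seed Integer seed.
#' @param bias Optional \code{env_grid} of proposal weights.
#' @return Data frame of \code{n} points. If fewer than \code{n} are
#'   accepted after \code{1000 * n} proposals, an infeasibility error naming
#'   \code{min_dist_km} is raised; short counts are never returned silently.
#' @export
generate_disk <- function(presences, domain, n, min_dist_km = 25, seed = 1,
                          bias = NULL) {
  stopifnot(inherits(domain, "env_grid"), n >= 0)
  if (nrow(presences) < 1L) stop("need at least one presence")
  if (n == 0L) return(data.frame(lon = numeric(0), lat = numeric(0)))
  cells <- unmasked_cells(domain)
  if (nrow(cells) == 0L) stop("domain mask leaves no cells")
  weights <- if (!is.null(bias)) bias$values[cbind(cells$row, cells$col)]
  set.seed(seed)
  accepted <- list()
  n_acc <- 0L
  proposed <- 0L
  cap <- 1000 * n
  while (n_acc < n) {
    batch <- min(max(n, 1000L), cap - proposed)
    if (batch <= 0L)
      stop(sprintf(paste0("infeasible disk configuration: %d of %d points ",
                          "accepted after %d proposals at min_dist_km = %g"),
                   n_acc, n, proposed, min_dist_km))
    cand <- propose_points(domain, batch, cells, weights)
    proposed <- proposed + batch
    keep <- dist_to_nearest_km(cand, presences) >= min_dist_km
    if (any(keep)) {
      accepted[[length(accepted) + 1L]] <- cand[keep, , drop = FALSE]
      n_acc <- n_acc + sum(keep)
    }
  }
  out <- do.call(rbind, accepted)[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Latitude-filtered random pseudo-absences
#'
#' Uniform points over unmasked cells, jittered within cells, keeping only
#' points north of \code{lat_threshold}: beyond the cold limit the species
#' is absent for climatic reasons, so random points there are safe absences.
#'
#' @param domain \code{env_grid} defining the study-area mask.
#' @param n Number of points.
#' @param lat_threshold Degrees latitude; returned points satisfy
#'   \code{lat > lat_threshold}.
#' @param seed Integer seed.
#' @return Data frame of \code{n} points; infeasibility error if no unmasked
#'   cell reaches north of the threshold.
#' @export
generate_random_filtered <- function(domain, n, lat_threshold = 64, seed = 1) {
  stopifnot(inherits(domain, "env_grid"), n >= 0)
  cells <- unmasked_cells(domain)
  cs <- domain$cellsize
  ytop <- domain$yllcorner + domain$nrows * cs
  north_edge <- ytop - (cells$row - 1) * cs
  cells <- cells[north_edge > lat_threshold, , drop = FALSE]
  if (nrow(cells) == 0L)
    stop("infeasible: no unmasked cells north of latitude ", lat_threshold)
  if (n == 0L) return(data.frame(lon = numeric(0), lat = numeric(0)))
  set.seed(seed)
  accepted <- list()
  n_acc <- 0L
  proposed <- 0L
  cap <- 1000 * n
  while (n_acc < n) {
    batch <- min(max(n, 1000L), cap - proposed)
    if (batch <= 0L)
      stop("infeasible: latitude filter > ", lat_threshold,
           " accepts too few points")
    cand <- propose_points(domain, batch, cells)
    proposed <- proposed + batch
    keep <- cand$lat > lat_threshold
    if (any(keep)) {
      accepted[[length(accepted) + 1L]] <- cand[keep, , drop = FALSE]
      n_acc <- n_acc + sum(keep)
    }
  }
  out <- do.call(rbind, accepted)[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the labelled training set
#'
#' Generates \code{round(disk_fraction * n_total)} disk pseudo-absences and
#' the remainder by the latitude-filtered random strategy, attaches labels
#' (1 = presence, 0 = pseudo-absence) and source tags, extracts the
#' covariate vector of every point from the stack, and drops points that are
#' outside the extent or on NODATA cells (the count of dropped points is
#' reported, never hidden).
#'
#' @param presences Data frame of (typically thinned) presence coordinates.
#' @param config A [pa_config()].
#' @param stack \code{env_stack} of covariates.
#' @return List with \code{occ} (data frame: lon, lat, label, source),
#'   \code{features} (covariate data frame, same rows as \code{occ}), and
#'   \code{n_dropped} (named count of invalid points removed per source).
#' @export
assemble_training_set <- function(presences, config, stack) {
  stopifnot(inherits(config, "pa_config"), inherits(stack, "env_stack"))
  mask <- stack_mask(stack)
  g <- stack[[1]]
  dom_vals <- matrix(1, g$nrows, g$ncols)
  dom_vals[mask] <- NA_real_
  domain <- env_grid(dom_vals, g$xllcorner, g$yllcorner, g$cellsize,
                     g$nodata_value)
  n_disk <- round(config$disk_fraction * config$n_total)
  n_rand <- config$n_total - n_disk
  disk <- generate_disk(presences, domain, n_disk,
                        min_dist_km = config$min_dist_km,
                        seed = config$seed + 1L, bias = config$bias)
  rand <- generate_random_filtered(domain, n_rand,
                                   lat_threshold = config$lat_threshold,
                                   seed = config$seed + 2L)
  pa <- rbind(
    if (nrow(disk)) cbind(disk, source = "pa_disk"),
    if (nrow(rand)) cbind(rand, source = "pa_random"))
  if (isTRUE(config$thin_pa) && nrow(pa) > 1L) {
    thinned <- thin_points(pa[, c("lon", "lat")], config$thin_distance_km,
                           iterations = 10, seed = config$seed + 3L)
    pa <- pa[thinned$retained, , drop = FALSE]
  }
  occ <- rbind(
    data.frame(lon = presences$lon, lat = presences$lat, label = 1L,
               source = "presence", stringsAsFactors = FALSE),
    data.frame(lon = pa$lon, lat = pa$lat, label = 0L, source = pa$source,
               stringsAsFactors = FALSE))
  ex <- extract_values(stack, occ)
  dropped <- table(occ$source[!ex$valid])
  if (sum(!ex$valid) > 0)
    message("assemble_training_set: dropped ", sum(!ex$valid),
            " point(s) with invalid covariates")
  occ <- occ[ex$valid, , drop = FALSE]
  feats <- ex$features[ex$valid, , drop = FALSE]
  rownames(occ) <- rownames(feats) <- NULL
  stopifnot(all(is.finite(as.matrix(feats))))
  list(occ = occ, features = feats,
       n_dropped = as.integer(sum(!ex$valid)), dropped_by_source = dropped)
}
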
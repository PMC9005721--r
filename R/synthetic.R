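# Synthetic environmental worlds with a known logistic suitability surface
# and accessibility-biased presence sampling, so every pipeline stage can be
# validated against ground truth without downloading real rasters.

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# 1-D convolution with reflection padding, output length == input length.
conv_reflect <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  xp <- c(x[pmin(n, pmax(1, r:1))], x, x[pmin(n, pmax(1, n:(n - r + 1)))])
  stats::convolve(xp, rev(k), type = "filter")
}

# Separable Gaussian blur of a matrix (reflection at edges).
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel(sigma)
  m <- t(apply(m, 1, conv_reflect, k = k))
  apply(m, 2, conv_reflect, k = k)
}

standardize <- function(m) (m - mean(m)) / stats::sd(m)

#' Generate a synthetic environmental stack
#'
#' Each base variable is spatially autocorrelated noise: white noise blurred
#' with a Gaussian kernel of \code{blur_cells} cells, then standardised to
#' mean 0, sd 1 over the grid. Within each correlation group the first
#' (leader) member is kept and every other member is rebuilt as
#' \code{leader + noise}, with the noise scaled so the empirical Pearson
#' correlation with the leader is at least 0.85 (target 0.92; the noise is
#' halved until the floor is met).
#'
#' An optional deterministic latitudinal gradient can be mixed into selected
#' variables before standardisation, emulating how real temperature-derived
#' bioclim variables decline towards the pole; gradients are applied before
#' correlate construction so grouped variables inherit them.
#'
#' @param extent Numeric vector \code{c(lon_min, lon_max, lat_min, lat_max)}.
#' @param cellsize Cell size in degrees.
#' @param n_vars Number of variables.
#' @param corr_groups List of integer or character index vectors; disjoint.
#' @param blur_cells Gaussian blur sd in cells (spatial autocorrelation
#'   scale).
#' @param lat_gradient Optional named numeric vector: weight of the
#'   standardised north-positive latitude field mixed into those variables
#'   (negative = colder northwards).
#' @param var_names Variable names; default \code{V1..Vn}.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An \code{env_stack} with no NODATA cells.
#' @export
make_env_stack <- function(extent, cellsize, n_vars,
                           corr_groups = list(), blur_cells = 2,
                           lat_gradient = NULL,
                           var_names = paste0("V", seq_len(n_vars)),
                           seed = 1) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            cellsize > 0, n_vars >= 1)
  nc <- as.integer(round((extent[2] - extent[1]) / cellsize))
  nr <- as.integer(round((extent[4] - extent[3]) / cellsize))
  if (nc < 2L || nr < 2L) stop("degenerate extent")
  if (length(var_names) != n_vars) stop("var_names length != n_vars")
  groups <- lapply(corr_groups, function(g) {
    if (is.character(g)) g <- match(g, var_names)
    g <- as.integer(g)
    if (anyNA(g) || any(g < 1L) || any(g > n_vars))
      stop("corr_groups index exceeds n_vars")
    g
  })
  if (anyDuplicated(unlist(groups))) stop("corr_groups must be disjoint")

  set.seed(seed)
  # north-positive standardised latitude field (constant along rows)
  ytop <- extent[3] + nr * cellsize
  lat_row <- ytop - (seq_len(nr) - 0.5) * cellsize
  lat_field <- standardize(matrix(lat_row, nr, nc))

  base <- vector("list", n_vars)
  for (v in seq_len(n_vars)) {
    f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), blur_cells)
    f <- standardize(f)
    w <- if (!is.null(lat_gradient)) lat_gradient[var_names[v]] else NA
    if (!is.na(w) && w != 0) f <- standardize(f + w * lat_field)
    base[[v]] <- f
  }
  for (g in groups) {
    leader <- base[[g[1]]]
    for (v in g[-1]) {
      sigma <- sqrt(1 / 0.92^2 - 1)     # target r = 0.92
      repeat {
        eps <- matrix(stats::rnorm(nr * nc), nr, nc)
        cand <- standardize(leader + sigma * eps)
        if (abs(stats::cor(as.vector(cand), as.vector(leader))) >= 0.85) break
        sigma <- sigma / 2
      }
      base[[v]] <- cand
    }
  }
  grids <- lapply(base, env_grid, xllcorner = extent[1], yllcorner = extent[3],
                  cellsize = cellsize)
  names(grids) <- var_names
  env_stack(grids)
}

#' Cellwise logistic suitability surface
#'
#' \code{p = logistic(intercept + sum(coef * value))} over the stack.
#'
#' @param stack An \code{env_stack}.
#' @param coefficients Named numeric vector; names must be stack variables.
#' @param intercept Scalar.
#' @return An \code{env_grid} of probabilities in [0, 1].
#' @export
true_suitability <- function(stack, coefficients, intercept = 0) {
  stopifnot(inherits(stack, "env_stack"))
  missing <- setdiff(names(coefficients), names(stack))
  if (length(missing))
    stop("coefficients name variables not in stack: ",
         paste(missing, collapse = ", "))
  g <- stack[[1]]
  logit <- matrix(intercept, g$nrows, g$ncols)
  for (v in names(coefficients))
    logit <- logit + coefficients[[v]] * stack[[v]]$values
  env_grid(stats::plogis(logit), g$xllcorner, g$yllcorner, g$cellsize,
           g$nodata_value)
}

#' Accessibility (sampling-effort) field
#'
#' Record density in citizen-science data tracks human population density;
#' this emulates it as a sum of exponentially decaying kernels around
#' population centres: \code{w(cell) = sum_centers exp(-d_km / decay_km)}.
#'
#' @param template An \code{env_grid} providing the geometry.
#' @param centers Data frame of centre coordinates (\code{lon}, \code{lat}).
#' @param decay_km e-folding distance of accessibility, km (> 0).
#' @return An \code{env_grid} of strictly positive weights.
#' @export
make_bias_field <- function(template, centers, decay_km) {
  stopifnot(inherits(template, "env_grid"))
  if (nrow(centers) < 1L) stop("need at least one center")
  if (!is.finite(decay_km) || decay_km <= 0) stop("decay_km must be > 0")
  cc <- cell_centers(template)
  w <- rep(0, nrow(cc))
  for (i in seq_len(nrow(centers)))
    w <- w + exp(-haversine_km(cc$lon, cc$lat,
                               centers$lon[i], centers$lat[i]) / decay_km)
  m <- matrix(w, template$nrows, template$ncols, byrow = TRUE)
  env_grid(m, template$xllcorner, template$yllcorner, template$cellsize,
           template$nodata_value)
}

#' Sample presence records biased by accessibility
#'
#' Cells are drawn multinomially with probability proportional to
#' \code{truth * bias} over unmasked cells; each record is then jittered
#' uniformly within its cell (real records are not cell-centred).
#'
#' @param truth Suitability \code{env_grid} (probabilities).
#' @param bias Sampling-effort \code{env_grid}, aligned with \code{truth}.
#' @param n Number of records.
#' @param seed Integer seed.
#' @return Data frame with columns \code{lon}, \code{lat}.
#' @export
sample_presences <- function(truth, bias, n, seed = 1) {
  stopifnot(inherits(truth, "env_grid"), inherits(bias, "env_grid"))
  if (!same_geometry(truth, bias)) stop("truth and bias grids not aligned")
  if (n == 0L) return(data.frame(lon = numeric(0), lat = numeric(0)))
  cc <- cell_centers(truth)
  tv <- as.vector(t(truth$values))   # row-major, matches cell_centers order
  bv <- as.vector(t(bias$values))
  p <- tv * bv
  p[is.na(p)] <- 0
  if (all(p == 0)) stop("sampling error: truth * bias is zero everywhere")
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, n, p))
  idx <- rep(seq_along(counts), counts)
  cs <- truth$cellsize
  lon_ll <- truth$xllcorner + (cc$col[idx] - 1) * cs
  lat_ll <- truth$yllcorner + (truth$nrows - cc$row[idx]) * cs
  data.frame(lon = lon_ll + stats::runif(length(idx)) * cs,
             lat = lat_ll + stats::runif(length(idx)) * cs)
}

#' Build a complete synthetic study system
#'
#' Defaults describe a toy version of a large north-temperate study region:
#' a 30 x 30 degree box (lon 30-60 E, lat 40-70 N) at 0.5 degree cells
#' (60 x 60), 19 bioclim-like plus 5 soil-like covariates, three informative
#' variables (two climatic, one soil: BIO1 +2, BIO8 +1.5, SOC +1.5, logit
#' intercept -0.5, a strongly climate-limited niche), a planted correlate of
#' an informative variable (BIO11 ~ BIO1) and a noise pair (BIO16 ~ BIO12),
#' a negative latitudinal gradient on the BIO1/BIO11 temperature pair,
#' sampling bias from 30 population centres scattered over the inhabited
#' part of the domain with a 100 km accessibility decay (drawn
#' deterministically from the seed when \code{bias_centers} is \code{NULL}),
#' and a northern strip (above 64 N) where true suitability is forced
#' towards zero (a tundra-like hard limit), implemented as a smooth logit
#' penalty.
#'
#' @param extent,cellsize Domain definition.
#' @param n_presences Number of biased presence records to sample.
#' @param coefficients,intercept Truth model; defaults as above.
#' @param corr_groups Planted correlation groups (names).
#' @param bias_centers,bias_decay_km Accessibility model; \code{NULL}
#'   centers are drawn from the seed (\code{n_centers} towns).
#' @param n_centers Number of population centres when drawn.
#' @param cold_lat Latitude above which truth is suppressed (degrees);
#'   \code{NA} disables the strip.
#' @param blur_cells Spatial autocorrelation scale of the covariates.
#' @param seed Master seed; all sub-stages derive from it.
#' @return An object of class \code{synthetic_world}: list with
#'   \code{stack}, \code{truth}, \code{bias}, \code{presences},
#'   \code{coefficients}, \code{intercept}, \code{informative}, \code{seed}.
#' @export
make_synthetic_world <- function(extent = c(30, 60, 40, 70), cellsize = 0.5,
                                 n_presences = 2000,
                                 coefficients = c(BIO1 = 2.0, BIO8 = 1.5,
                                                  SOC = 1.5),
                                 intercept = -0.5,
                                 corr_groups = list(c("BIO1", "BIO11"),
                                                    c("BIO12", "BIO16")),
                                 bias_centers = NULL,
                                 bias_decay_km = 100,
                                 n_centers = 30,
                                 cold_lat = 64,
                                 blur_cells = 2,
                                 seed = 1) {
  var_names <- c(paste0("BIO", 1:19), "Silt", "Sand", "CF", "CEC", "SOC")
  if (is.null(bias_centers)) {
    # towns scattered over the inhabited (non-tundra) part of the domain
    set.seed(seed + 2L)
    south <- if (is.na(cold_lat)) extent[4] else min(cold_lat - 1, extent[4])
    bias_centers <- data.frame(
      lon = stats::runif(n_centers, extent[1] + 1, extent[2] - 1),
      lat = extent[3] + 1 +
        (south - extent[3] - 2) * stats::rbeta(n_centers, 1.3, 1.3))
  }
  stack <- make_env_stack(extent, cellsize, length(var_names),
                          corr_groups = corr_groups, blur_cells = blur_cells,
                          lat_gradient = c(BIO1 = -1.0, BIO11 = -1.0),
                          var_names = var_names, seed = seed)
  truth <- true_suitability(stack, coefficients, intercept)
  if (!is.na(cold_lat)) {
    # smooth logit penalty ramping in over ~2 degrees north of cold_lat
    cc <- cell_centers(truth)
    ramp <- pmin(1, pmax(0, (cc$lat - cold_lat) / 2))
    logit <- stats::qlogis(pmin(1 - 1e-12, pmax(1e-12, as.vector(t(truth$values)))))
    p <- stats::plogis(logit - 8 * ramp)
    truth <- env_grid(matrix(p, truth$nrows, truth$ncols, byrow = TRUE),
                      truth$xllcorner, truth$yllcorner, truth$cellsize,
                      truth$nodata_value)
  }
  bias <- make_bias_field(truth, bias_centers, bias_decay_km)
  presences <- sample_presences(truth, bias, n_presences, seed = seed + 1)
  structure(list(stack = stack, truth = truth, bias = bias,
                 presences = presences, coefficients = coefficients,
                 intercept = intercept, informative = names(coefficients),
                 corr_groups = corr_groups, cold_lat = cold_lat, seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  g <- x$stack[[1]]
  cat(sprintf("synthetic_world: %d x %d grid, %d covariates, %d presences (seed %d)\n",
              g$nrows, g$ncols, length(x$stack), nrow(x$presences), x$seed))
  cat("  informative:", paste(x$informative, collapse = ", "), "\n")
  invisible(x)
}

#' Perturbed "future" climate stack
#'
#' Produces an opaque future scenario by shifting temperature-like variables
#' of the present stack by a constant (in standardised units), optionally
#' only within a latitude band; all other variables are carried over
#' unchanged. This stands in for an external climate-model stack.
#'
#' @param stack Present \code{env_stack}.
#' @param warming Shift added to each temperature-like variable.
#' @param temp_vars Variables to shift.
#' @param lat_range Optional \code{c(min, max)} latitude band to restrict the
#'   shift to (cell centres).
#' @return An \code{env_stack}.
#' @export
make_future_stack <- function(stack, warming = 1.0,
                              temp_vars = c("BIO1", "BIO8", "BIO10", "BIO11"),
                              lat_range = NULL) {
  stopifnot(inherits(stack, "env_stack"))
  temp_vars <- intersect(temp_vars, names(stack))
  g <- stack[[1]]
  add <- matrix(warming, g$nrows, g$ncols)
  if (!is.null(lat_range)) {
    cc <- cell_centers(g)
    inband <- cc$lat >= lat_range[1] & cc$lat <= lat_range[2]
    add <- add * matrix(as.numeric(inband), g$nrows, g$ncols, byrow = TRUE)
  }
  out <- lapply(names(stack), function(v) {
    gr <- stack[[v]]
    if (v %in% temp_vars)
      env_grid(gr$values + add, gr$xllcorner, gr$yllcorner, gr$cellsize,
               gr$nodata_value)
    else gr
  })
  names(out) <- names(stack)
  env_stack(out)
}

#' Write a synthetic world to disk
#'
#' One .asc file per covariate plus \code{truth.asc}, \code{bias.asc} and
#' \code{presences.csv}, so the pipeline can be run end-to-end from files.
#'
#' @param world A \code{synthetic_world}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in names(world$stack))
    write_ascii_grid(world$stack[[v]], file.path(dir, paste0(v, ".asc")))
  write_ascii_grid(world$truth, file.path(dir, "truth.asc"))
  write_ascii_grid(world$bias, file.path(dir, "bias.asc"))
  utils::write.csv(world$presences, file.path(dir, "presences.csv"),
                   row.names = FALSE)
  invisible(dir)
}
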
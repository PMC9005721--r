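# Final model fitting, habitat-suitability map projection for present and
# substituted future climate stacks, and the map summaries used to report
# them (band fractions, mean/max suitability, block variability).

#' Fit the final suitability model on all assembled data
#'
#' @param features Covariate data frame (all training rows).
#' @param labels Binary labels (0/1).
#' @param selected_vars Character vector of covariates to use; must all be
#'   columns of \code{features}.
#' @param rf_params randomForest overrides (default 500 trees, sqrt(p)
#'   variables per split).
#' @param seed Integer seed.
#' @return Object of class \code{sdm_model} wrapping the forest with its
#'   variable ordering.
#' @export
fit_final_model <- function(features, labels, selected_vars,
                            rf_params = list(), seed = 1) {
  missing <- setdiff(selected_vars, colnames(features))
  if (length(missing))
    stop("selected variables not in feature table: ",
         paste(missing, collapse = ", "))
  x <- features[, selected_vars, drop = FALSE]
  rf <- rf_fit(x, labels, rf_params, seed = seed)
  structure(list(rf = rf, selected_vars = selected_vars, seed = seed,
                 rf_params = default_rf_params(length(selected_vars),
                                               rf_params)),
            class = "sdm_model")
}

#' Predict scores for a feature table
#'
#' @param object An \code{sdm_model}.
#' @param newdata Data frame containing at least the model's variables.
#' @param ... Unused.
#' @return Vector of presence probabilities.
#' @export
predict.sdm_model <- function(object, newdata, ...) {
  missing <- setdiff(object$selected_vars, colnames(newdata))
  if (length(missing))
    stop("newdata lacks variable(s): ", paste(missing, collapse = ", "))
  rf_prob(object$rf, newdata[, object$selected_vars, drop = FALSE])
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("sdm_model: random forest (%d trees) on %d variables\n",
              x$rf_params$ntree, length(x$selected_vars)))
  cat("  ", paste(x$selected_vars, collapse = ", "), "\n")
  invisible(x)
}

#' Carry soil layers into a future stack
#'
#' Soil properties change far more slowly than climate, so future scenarios
#' reuse the present-day soil grids: this replaces (or adds) the named soil
#' variables in \code{future} with the grids from \code{present}.
#'
#' @param future \code{env_stack} of future bioclim layers.
#' @param present Present-day \code{env_stack} holding the soil layers.
#' @param soil_vars Soil variable names (default the package's five:
#'   Silt, Sand, CF, CEC, SOC).
#' @return Combined \code{env_stack}.
#' @export
carry_over_soil <- function(future, present,
                            soil_vars = c("Silt", "Sand", "CF", "CEC",
                                          "SOC")) {
  stopifnot(inherits(future, "env_stack"), inherits(present, "env_stack"))
  soil_vars <- intersect(soil_vars, names(present))
  out <- unclass(future)
  for (v in soil_vars) out[[v]] <- present[[v]]
  env_stack(out)
}

#' Project a suitability map
#'
#' Predicts the presence probability of every unmasked cell of the stack
#' (union NODATA mask); masked cells stay NODATA.
#'
#' @param model An \code{sdm_model}.
#' @param stack \code{env_stack} containing every model variable (for future
#'   stacks, combine with [carry_over_soil()] first).
#' @param scenario Free-text provenance tag (e.g. \code{"present"},
#'   \code{"canesm5-ssp585"}).
#' @return Object of class \code{suitability_map}: \code{grid}
#'   (\code{env_grid} of probabilities), \code{scenario},
#'   \code{selected_vars}.
#' @export
project_suitability <- function(model, stack, scenario = "present") {
  stopifnot(inherits(model, "sdm_model"), inherits(stack, "env_stack"))
  missing <- setdiff(model$selected_vars, names(stack))
  if (length(missing))
    stop("stack lacks model variable(s): ", paste(missing, collapse = ", "))
  g <- stack[[1]]
  mask <- stack_mask(env_stack(stack[model$selected_vars]))
  keep <- which(!as.vector(mask))   # column-major cell indices
  newdata <- as.data.frame(lapply(stack[model$selected_vars],
                                  function(gr) gr$values[keep]))
  names(newdata) <- model$selected_vars
  vals <- matrix(NA_real_, g$nrows, g$ncols)
  if (length(keep)) vals[keep] <- predict(model, newdata)
  out <- env_grid(vals, g$xllcorner, g$yllcorner, g$cellsize, g$nodata_value)
  structure(list(grid = out, scenario = scenario,
                 selected_vars = model$selected_vars),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$grid$values
  cat(sprintf("suitability_map [%s]: mean %.3f, max %.3f over %d cells\n",
              x$scenario, mean(v, na.rm = TRUE), max(v, na.rm = TRUE),
              sum(!is.na(v))))
  invisible(x)
}

#' Summarise a suitability map
#'
#' Reports the reporting-band fractions over unmasked cells (below
#' \code{low}, above \code{high}; the three bands partition the cells), the
#' mean and maximum suitability, and the spatial variability of the
#' predictions: the mean over \code{block_km} blocks (on cell centres) of
#' the within-block standard deviation.
#'
#' @param map A \code{suitability_map} or probability \code{env_grid}.
#' @param low,high Band thresholds (defaults 0.25 and 0.5).
#' @param block_km Block edge for the variability diagnostic (default 100).
#' @return Object of class \code{area_summary} (a one-row data frame with
#'   columns \code{fraction_below_low}, \code{fraction_mid},
#'   \code{fraction_above_high}, \code{mean_suitability},
#'   \code{max_suitability}, \code{block_variability}).
#' @export
summarize_map <- function(map, low = 0.25, high = 0.5, block_km = 100) {
  g <- if (inherits(map, "suitability_map")) map$grid else map
  stopifnot(inherits(g, "env_grid"))
  cc <- cell_centers(g)
  v <- g$values[cbind(cc$row, cc$col)]
  ok <- !is.na(v)
  if (!any(ok)) stop("summary undefined: map is fully masked")
  v <- v[ok]
  tiling <- block_tiling(g$xllcorner, g$yllcorner, block_km,
                         lat_ref = g$yllcorner + g$nrows * g$cellsize / 2)
  keys <- block_index(tiling, cc$lon[ok], cc$lat[ok])$key
  sds <- tapply(v, keys, function(x) if (length(x) > 1) stats::sd(x) else NA)
  sds <- sds[!is.na(sds)]
  out <- data.frame(
    fraction_below_low = mean(v < low),
    fraction_mid = mean(v >= low & v <= high),
    fraction_above_high = mean(v > high),
    mean_suitability = mean(v),
    max_suitability = max(v),
    block_variability = if (length(sds)) mean(sds) else 0,
    low = low, high = high, block_km = block_km)
  class(out) <- c("area_summary", "data.frame")
  out
}

#' Compare suitability maps across scenarios
#'
#' @param maps Named (or scenario-tagged) list of aligned
#'   \code{suitability_map} objects; the first is the reference (present).
#' @param ... Passed to [summarize_map()].
#' @return List with \code{table} (one \code{area_summary} row per
#'   scenario) and \code{diff_maps} (cellwise \code{env_grid} differences,
#'   scenario minus reference, for every non-reference map).
#' @export
compare_scenarios <- function(maps, ...) {
  stopifnot(length(maps) >= 1)
  tags <- vapply(seq_along(maps), function(i) {
    if (!is.null(names(maps)) && nzchar(names(maps)[i])) names(maps)[i]
    else maps[[i]]$scenario
  }, character(1))
  ref <- maps[[1]]$grid
  for (m in maps)
    if (!same_geometry(m$grid, ref))
      stop("maps are not aligned (header geometry differs)")
  tab <- do.call(rbind, lapply(maps, summarize_map, ...))
  tab <- cbind(scenario = tags, tab)
  rownames(tab) <- NULL
  diffs <- lapply(maps[-1], function(m)
    env_grid(m$grid$values - ref$values, ref$xllcorner, ref$yllcorner,
             ref$cellsize, ref$nodata_value))
  names(diffs) <- tags[-1]
  list(table = tab, diff_maps = diffs)
}
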
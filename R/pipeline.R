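# End-to-end orchestration: thin -> pseudo-absences -> feature selection ->
# spatial CV -> final fit -> projection -> summaries, under one config and
# one seed, with a manifest recording every stage.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default: thinning
#' distances 4/7/10 km (100 iterations, final model at 7 km), 1:1
#' pseudo-absences (half disk at 25 km, half random north of 64 degrees),
#' correlation threshold 0.8, 13-fold spatial CV on 100-km blocks repeated
#' 20 times, report bands 0.25/0.5. Stage seeds are derived from the single
#' global seed.
#'
#' @param thin_distances_km Candidate thinning distances (preset 4, 7, 10).
#' @param thin_iterations Thinning restarts (default 100).
#' @param final_distance_km Distance used for the final model (default 7).
#' @param pa List of pseudo-absence settings passed to [pa_config()]
#'   (\code{n_total} defaults to the thinned presence count).
#' @param corr_threshold Correlation-grouping threshold (default 0.8).
#' @param cv List: \code{block_km} (100), \code{k} (13), \code{repeats}
#'   (20).
#' @param rf_params randomForest overrides (default 500 trees).
#' @param bands Report thresholds \code{c(low, high)} (0.25, 0.5).
#' @param selected_override Optional character vector of variable names: a
#'   manual final feature list that skips automatic selection (e.g. a
#'   published list such as SOC, CEC, BIO1, BIO8, BIO10, BIO13, BIO15,
#'   BIO19).
#' @param n_permutations MDA permutation repeats in selection.
#' @param seed Global seed.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(thin_distances_km = c(4, 7, 10),
                            thin_iterations = 100,
                            final_distance_km = 7,
                            pa = list(),
                            corr_threshold = 0.8,
                            cv = list(block_km = 100, k = 13, repeats = 20),
                            rf_params = list(),
                            bands = c(0.25, 0.5),
                            selected_override = NULL,
                            n_permutations = 10,
                            seed = 1) {
  cv_def <- list(block_km = 100, k = 13, repeats = 20)
  cv_def[names(cv)] <- cv
  if (!is.null(selected_override) && !is.character(selected_override))
    stop("selected_override must be a character vector of variable names")
  structure(list(thin_distances_km = thin_distances_km,
                 thin_iterations = thin_iterations,
                 final_distance_km = final_distance_km, pa = pa,
                 corr_threshold = corr_threshold, cv = cv_def,
                 rf_params = rf_params, bands = bands,
                 selected_override = selected_override,
                 n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_record <- function(name, seed, params, outputs) {
  list(name = name, seed = seed, params = params, outputs = outputs,
       hash = rlang::hash(outputs))
}

#' Run the full analysis pipeline
#'
#' Executes thin, background (pseudo-absence assembly), select, cv, fit,
#' project and summarize in sequence and returns every artefact plus a
#' manifest of the seven stage records (each with its derived seed, the
#' parameters in effect and a hash of its outputs). Reruns with the same
#' inputs and config reproduce the same manifest hashes.
#'
#' @param presences Data frame of presence records (\code{lon}, \code{lat}).
#' @param stack Present-climate \code{env_stack}.
#' @param config A [pipeline_config()].
#' @param future_stacks Optional named list of future \code{env_stack}s
#'   (bioclim layers; soil layers are carried over from \code{stack}
#'   automatically).
#' @return Object of class \code{sdm_run}: \code{thinned}, \code{training},
#'   \code{selection}, \code{cv}, \code{model}, \code{maps} (present first),
#'   \code{summaries}, \code{manifest}, \code{config}.
#' @export
run_pipeline <- function(presences, stack, config = pipeline_config(),
                         future_stacks = list()) {
  stopifnot(inherits(config, "pipeline_config"), inherits(stack, "env_stack"))
  seed <- config$seed
  manifest <- list()
  push <- function(rec) manifest[[length(manifest) + 1L]] <<- rec
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  # 1. thin
  thinned <- tryCatch(
    thin_points(presences, config$final_distance_km,
                iterations = config$thin_iterations, seed = seed + 101L),
    error = function(e) fail("thin", e))
  push(stage_record("thin", seed + 101L,
                    list(distance_km = config$final_distance_km,
                         iterations = config$thin_iterations),
                    list(n_in = nrow(presences),
                         n_retained = length(thinned$retained))))

  # 2. background (pseudo-absences + covariate extraction)
  training <- tryCatch({
    pa_args <- config$pa
    if (is.null(pa_args$n_total)) pa_args$n_total <- length(thinned$retained)
    pa_args$seed <- seed + 202L
    cfg <- do.call(pa_config, pa_args)
    assemble_training_set(thinned$points, cfg, stack)
  }, error = function(e) fail("background", e))
  push(stage_record("background", seed + 202L,
                    config$pa,
                    list(n_rows = nrow(training$occ),
                         class_balance = mean(training$occ$label),
                         n_dropped = training$n_dropped)))

  # 3. select
  selection <- tryCatch({
    if (!is.null(config$selected_override)) {
      missing <- setdiff(config$selected_override, names(stack))
      if (length(missing))
        stop("selected_override names unknown variable(s): ",
             paste(missing, collapse = ", "))
      list(selected = config$selected_override, audit = list(
        list(decision = "manual override", variables = config$selected_override)))
    } else {
      select_features(training$features, training$occ$label,
                      coords = training$occ, threshold = config$corr_threshold,
                      rf_params = config$rf_params,
                      n_permutations = config$n_permutations,
                      seed = seed + 303L)
    }
  }, error = function(e) fail("select", e))
  push(stage_record("select", seed + 303L,
                    list(threshold = config$corr_threshold,
                         override = !is.null(config$selected_override)),
                    list(selected = selection$selected)))

  # 4. cv
  cv_rep <- tryCatch({
    folds <- make_folds(training$occ, block_km = config$cv$block_km,
                        k = config$cv$k, repeats = config$cv$repeats,
                        seed = seed + 404L)
    cross_validate(training$features[, selection$selected, drop = FALSE],
                   training$occ$label, folds, rf_params = config$rf_params,
                   seed = seed + 404L)
  }, error = function(e) fail("cv", e))
  push(stage_record("cv", seed + 404L, config$cv,
                    list(auc_mean = cv_rep$auc_mean, auc_sd = cv_rep$auc_sd,
                         n_skipped = cv_rep$n_skipped)))

  # 5. fit
  model <- tryCatch(
    fit_final_model(training$features, training$occ$label,
                    selection$selected, rf_params = config$rf_params,
                    seed = seed + 505L),
    error = function(e) fail("fit", e))
  push(stage_record("fit", seed + 505L, config$rf_params,
                    list(selected = selection$selected)))

  # 6. project (present + futures, soil carried over)
  maps <- tryCatch({
    out <- list(present = project_suitability(model, stack, "present"))
    for (tag in names(future_stacks)) {
      fs <- carry_over_soil(future_stacks[[tag]], stack)
      out[[tag]] <- project_suitability(model, fs, tag)
    }
    out
  }, error = function(e) fail("project", e))
  push(stage_record("project", seed, list(scenarios = names(maps)),
                    lapply(maps, function(m)
                      mean(m$grid$values, na.rm = TRUE))))

  # 7. summarize
  summaries <- tryCatch(
    compare_scenarios(maps, low = config$bands[1], high = config$bands[2],
                      block_km = config$cv$block_km),
    error = function(e) fail("summarize", e))
  push(stage_record("summarize", seed,
                    list(bands = config$bands),
                    summaries$table))

  structure(list(thinned = thinned, training = training,
                 selection = selection, cv = cv_rep, model = model,
                 maps = maps, summaries = summaries, manifest = manifest,
                 config = config,
                 versions = list(r = R.version.string,
                                 spatSDM = as.character(
                                   utils::packageVersion("spatSDM")))),
            class = "sdm_run")
}

#' @export
print.sdm_run <- function(x, ...) {
  cat("sdm_run with stages:",
      paste(vapply(x$manifest, `[[`, "", "name"), collapse = " -> "), "\n")
  cat(sprintf("  %d -> %d presences after thinning at %g km\n",
              x$manifest[[1]]$outputs$n_in, length(x$thinned$retained),
              x$config$final_distance_km))
  cat(sprintf("  selected: %s\n", paste(x$selection$selected, collapse = ", ")))
  cat(sprintf("  spatial CV AUC %.3f +/- %.3f\n", x$cv$auc_mean, x$cv$auc_sd))
  invisible(x)
}

#' Thinning-distance sweep
#'
#' Builds the four-way design used to choose a thinning distance: the
#' unthinned presences plus one thinned set per preset distance, then runs
#' the downstream comparison via [compare_thinnings()].
#'
#' @param presences Presence data frame.
#' @param stack \code{env_stack}.
#' @param config A [pipeline_config()].
#' @param truth Optional truth grid for RMSE reporting.
#' @return A \code{thinning_comparison}.
#' @export
run_thinning_sweep <- function(presences, stack, config = pipeline_config(),
                               truth = NULL) {
  sets <- list("0" = presences)
  for (d in config$thin_distances_km) {
    th <- thin_points(presences, d, iterations = config$thin_iterations,
                      seed = config$seed + 101L)
    sets[[as.character(d)]] <- th$points
  }
  compare_thinnings(sets, stack, truth = truth, pa = config$pa,
                    cv = list(block_km = config$cv$block_km, k = 5,
                              repeats = 2),
                    rf_params = config$rf_params, bands = config$bands,
                    seed = config$seed)
}
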
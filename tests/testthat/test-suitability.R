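fitted_toy <- function(seed = 61) {
  w <- small_world(seed = seed, n_presences = 200)
  th <- thin_points(w$presences, 7, iterations = 5, seed = 1)
  cfg <- pa_config(n_total = length(th$retained), lat_threshold = 58, seed = 2)
  tr <- assemble_training_set(th$points, cfg, w$stack)
  model <- fit_final_model(tr$features, tr$occ$label,
                           c("BIO1", "BIO8", "SOC"),
                           rf_params = list(ntree = 200), seed = 3)
  list(w = w, tr = tr, model = model)
}

test_that("projection reproduces per-row training scores and is deterministic", {
  f <- fitted_toy()
  map <- project_suitability(f$model, f$w$stack)
  expect_true(all(map$grid$values >= 0 & map$grid$values <= 1))
  ex <- extract_values(env_stack(list(p = map$grid)), f$tr$occ)
  expect_equal(ex$features$p, predict(f$model, f$tr$features),
               tolerance = 1e-12)
  # in-sample discrimination on a planted world is strong
  expect_gt(roc_auc(predict(f$model, f$tr$features), f$tr$occ$label), 0.9)
  m2 <- fit_final_model(f$tr$features, f$tr$occ$label,
                        c("BIO1", "BIO8", "SOC"),
                        rf_params = list(ntree = 200), seed = 3)
  map2 <- project_suitability(m2, f$w$stack)
  expect_identical(map$grid$values, map2$grid$values)
})

test_that("projection is invariant to stack variable order and names misses", {
  f <- fitted_toy(62)
  shuffled <- env_stack(unclass(f$w$stack)[rev(names(f$w$stack))])
  m1 <- project_suitability(f$model, f$w$stack)
  m2 <- project_suitability(f$model, shuffled)
  expect_identical(m1$grid$values, m2$grid$values)
  tiny <- env_stack(unclass(f$w$stack)[c("BIO1", "BIO8")])
  expect_error(project_suitability(f$model, tiny), "SOC")
  expect_error(fit_final_model(f$tr$features, f$tr$occ$label,
                               c("BIO1", "nope")), "nope")
})

test_that("NODATA cells stay masked in projections", {
  f <- fitted_toy(63)
  st <- unclass(f$w$stack)
  st$BIO1$values[3, 4] <- NA
  map <- project_suitability(f$model, env_stack(st))
  expect_true(is.na(map$grid$values[3, 4]))
  expect_equal(sum(is.na(map$grid$values)), 1L)
})

test_that("an identical 'future' stack projects to an identical map", {
  f <- fitted_toy(64)
  present <- project_suitability(f$model, f$w$stack, "present")
  future <- project_suitability(f$model, make_future_stack(f$w$stack, 0),
                                "future-null")
  expect_identical(present$grid$values, future$grid$values)
})

test_that("soil layers are carried over unchanged into future stacks", {
  f <- fitted_toy(65)
  fut <- make_future_stack(f$w$stack, warming = 1)
  fut_soil_zeroed <- unclass(fut)
  fut_soil_zeroed$SOC$values[] <- 0
  combined <- carry_over_soil(env_stack(fut_soil_zeroed), f$w$stack)
  expect_identical(combined$SOC$values, f$w$stack$SOC$values)
  expect_identical(combined$CEC$values, f$w$stack$CEC$values)
  expect_equal(combined$BIO1$values, f$w$stack$BIO1$values + 1)
})

test_that("map summaries match a brute-force cell loop and conserve mass", {
  # uniform map: everything in the middle band, zero variability
  uni <- env_grid(matrix(0.3, 10, 10), 40, 50, 0.5)
  s <- summarize_map(uni)
  expect_identical(s$fraction_below_low, 0)
  expect_identical(s$fraction_above_high, 0)
  expect_equal(s$mean_suitability, 0.3)
  expect_identical(s$block_variability, 0)
  # two-level map
  two <- env_grid(matrix(rep(c(0.1, 0.6), each = 50), 10, 10), 40, 50, 0.5)
  s2 <- summarize_map(two)
  expect_equal(s2$fraction_below_low, 0.5)
  expect_equal(s2$fraction_above_high, 0.5)
  expect_equal(s2$mean_suitability, 0.35)
  # random maps against the oracle, exact
  set.seed(66)
  for (i in 1:5) {
    vals <- matrix(runif(400), 20, 20)
    vals[sample(400, 30)] <- NA
    g <- env_grid(vals, 30, 45, 0.5)
    s3 <- summarize_map(g)
    o <- bf_band_summary(g, 0.25, 0.5)
    expect_identical(s3$fraction_below_low, o$fraction_below_low)
    expect_identical(s3$fraction_mid, o$fraction_mid)
    expect_identical(s3$fraction_above_high, o$fraction_above_high)
    expect_equal(s3$mean_suitability, o$mean_suitability, tolerance = 1e-15)
    expect_identical(s3$max_suitability, o$max_suitability)
    expect_equal(s3$fraction_below_low + s3$fraction_mid +
                   s3$fraction_above_high, 1, tolerance = 1e-12)
  }
  expect_error(summarize_map(env_grid(matrix(NA_real_, 2, 2), 0, 0, 1)),
               "fully masked")
})

test_that("scenario comparison yields per-scenario rows and exact difference maps", {
  f <- fitted_toy(67)
  present <- project_suitability(f$model, f$w$stack, "present")
  fut <- project_suitability(
    f$model, make_future_stack(f$w$stack, 1), "warm")
  cmp <- compare_scenarios(list(present = present, warm = fut),
                           block_km = 100)
  expect_identical(nrow(cmp$table), 2L)
  expect_identical(cmp$table$scenario, c("present", "warm"))
  expect_length(cmp$diff_maps, 1)
  # linearity: mean of the difference equals difference of the means
  dm <- cmp$diff_maps$warm
  expect_equal(mean(dm$values),
               mean(fut$grid$values) - mean(present$grid$values),
               tolerance = 1e-12)
  same <- compare_scenarios(list(present = present, again = present))
  expect_true(all(same$diff_maps$again$values == 0))
  misaligned <- project_suitability(
    f$model, make_env_stack(c(40, 50, 49, 59), 0.5, 24,
                            var_names = names(f$w$stack), seed = 1), "bad")
  expect_error(compare_scenarios(list(present, misaligned)), "aligned")
})
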
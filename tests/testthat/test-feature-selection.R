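make_labelled_table <- function(n = 500, p = 8, seed = 1, signal_var = 1,
                                threshold = 0) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- paste0("x", seq_len(p))
  y <- as.integer(x[[signal_var]] > threshold)
  list(x = x, y = y)
}

test_that("correlation grouping matches a brute-force Pearson computation", {
  set.seed(41)
  x <- as.data.frame(matrix(rnorm(300 * 6), 300, 6))
  names(x) <- letters[1:6]
  cg <- correlation_groups(x, threshold = 0.8)
  expect_equal(cg$matrix, bf_pearson(x), tolerance = 1e-10)
  # independent noise columns: all singletons at 0.8
  expect_true(all(lengths(cg$groups) == 1))
})

test_that("correlated columns are grouped and zero variance is flagged", {
  set.seed(42)
  x <- data.frame(a = rnorm(200))
  x$b <- x$a                                   # duplicate: r = 1
  x$c <- x$a + rnorm(200, sd = 0.3)            # r ~ 0.96
  x$d <- rnorm(200)
  cg <- correlation_groups(x, 0.8)
  grp <- cg$groups[[which(vapply(cg$groups, function(g) "a" %in% g,
                                 logical(1)))]]
  expect_setequal(grp, c("a", "b", "c"))
  expect_equal(cg$matrix["a", "b"], 1)
  x$z <- 5
  expect_warning(cg2 <- correlation_groups(x, 0.8), "zero-variance")
  expect_identical(cg2$excluded, "z")
  # engineered pair from the generator is grouped
  s <- make_env_stack(c(40, 50, 50, 60), 0.5, 5,
                      corr_groups = list(c(2, 4)), seed = 1)
  feats <- as.data.frame(lapply(s, function(g) as.vector(g$values)))
  cg3 <- correlation_groups(feats, 0.8)
  grp3 <- cg3$groups[[which(vapply(cg3$groups, function(g) "V2" %in% g,
                                   logical(1)))]]
  expect_setequal(grp3, c("V2", "V4"))
})

test_that("planted signal is ranked first by both MDG and MDA", {
  d <- make_labelled_table(n = 500, p = 8, seed = 43, signal_var = 3)
  imp <- rf_importance(d$x, d$y, rf_params = list(ntree = 200),
                      n_permutations = 5, seed = 1)
  expect_identical(imp$rank_mdg[imp$variable == "x3"], 1L)
  expect_identical(imp$rank_mda[imp$variable == "x3"], 1L)
  expect_true(all(sort(imp$rank_mdg) == 1:8))
  expect_true(all(sort(imp$rank_mda) == 1:8))
  # pure-noise variables: permutation importance fluctuates around zero
  noise_mda <- imp$mda[imp$variable != "x3"]
  expect_lt(max(abs(noise_mda)), 0.05)
  expect_gt(imp$mda[imp$variable == "x3"], 0.2)
  expect_error(rf_importance(d$x, rep(1, 500)), "single class")
})

test_that("permutation importance agrees with the forest's own measure in rank", {
  d <- make_labelled_table(n = 400, p = 6, seed = 44, signal_var = 2)
  d$y <- as.integer(d$x$x2 + 0.7 * d$x$x5 + rnorm(400, sd = 0.5) > 0)
  imp <- rf_importance(d$x, d$y, rf_params = list(ntree = 300),
                      n_permutations = 5, seed = 2)
  rf <- randomForest::randomForest(d$x, factor(d$y), ntree = 300,
                                   importance = TRUE)
  ref <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  # both measures put the two genuinely informative variables on top
  expect_setequal(imp$variable[imp$rank_mda <= 2], c("x2", "x5"))
  expect_setequal(names(sort(ref, decreasing = TRUE))[1:2], c("x2", "x5"))
})

test_that("duplicating an informative variable dilutes its Gini importance", {
  d <- make_labelled_table(n = 400, p = 5, seed = 45, signal_var = 1)
  solo <- rf_importance(d$x, d$y, rf_params = list(ntree = 300),
                        n_permutations = 1, seed = 3)
  mdg_solo <- solo$mdg[solo$variable == "x1"]
  dup <- d$x
  dup$x1copy <- dup$x1
  both <- rf_importance(dup, d$y, rf_params = list(ntree = 300),
                        n_permutations = 1, seed = 3)
  m1 <- both$mdg[both$variable == "x1"]
  m2 <- both$mdg[both$variable == "x1copy"]
  expect_lt(m1, mdg_solo)
  expect_lt(m2, mdg_solo)
  expect_gte(m1 + m2, max(m1, m2))
  expect_gt(min(m1, m2), 0)
})

test_that("selection keeps at most one member per group and is deterministic", {
  set.seed(46)
  n <- 400
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  x$a2 <- x$a + rnorm(n, sd = 0.3)            # correlate of the signal
  x$c2 <- x$c + rnorm(n, sd = 0.3)            # correlate of noise
  y <- as.integer(x$a + x$b > 0)
  sel1 <- select_features(x, y, rf_params = list(ntree = 200),
                          n_permutations = 3,
                          tiebreak = list(k = 3, repeats = 1, block_km = 100,
                                          rf_params = list(ntree = 100)),
                          seed = 5)
  cg <- sel1$groups
  for (g in Filter(function(g) length(g) > 1, cg$groups))
    expect_lte(sum(g %in% sel1$selected), 1)
  expect_true(any(c("a", "a2") %in% sel1$selected))
  expect_true("b" %in% sel1$selected)
  sel2 <- select_features(x, y, rf_params = list(ntree = 200),
                          n_permutations = 3,
                          tiebreak = list(k = 3, repeats = 1, block_km = 100,
                                          rf_params = list(ntree = 100)),
                          seed = 5)
  expect_identical(sel1$selected, sel2$selected)
  # the audit log records a decision for every variable
  audited <- vapply(sel1$audit, `[[`, "", "variable")
  expect_setequal(audited, names(x))
})

test_that("singletons are kept exactly when they reach the top half of a ranking", {
  d <- make_labelled_table(n = 400, p = 6, seed = 47, signal_var = 4)
  sel <- select_features(d$x, d$y, rf_params = list(ntree = 200),
                         n_permutations = 3, seed = 6)
  imp <- sel$importance
  half <- ceiling(nrow(imp) / 2)
  should_keep <- imp$variable[imp$rank_mdg <= half | imp$rank_mda <= half]
  expect_setequal(sel$selected, should_keep)
  expect_true("x4" %in% sel$selected)
})

test_that("audit logs serialise to JSON and a manual list is honoured", {
  d <- make_labelled_table(n = 300, p = 4, seed = 48)
  sel <- select_features(d$x, d$y, rf_params = list(ntree = 100),
                         n_permutations = 2, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_audit_log(sel, f)
  parsed <- jsonlite::read_json(f)
  expect_identical(unlist(parsed$selected), sel$selected)
  # a published 8-variable list is a valid override in the pipeline config
  cfg <- pipeline_config(selected_override = c("SOC", "CEC", "BIO1", "BIO8",
                                               "BIO10", "BIO13", "BIO15",
                                               "BIO19"))
  expect_identical(length(cfg$selected_override), 8L)
  expect_error(pipeline_config(selected_override = 1:3), "character")
})
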
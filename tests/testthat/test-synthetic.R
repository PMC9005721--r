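test_that("stack generation is deterministic and respects correlation groups", {
  ex <- c(40, 50, 50, 60)
  s1 <- make_env_stack(ex, 0.5, 6, corr_groups = list(c(1, 2)), seed = 3)
  s2 <- make_env_stack(ex, 0.5, 6, corr_groups = list(c(1, 2)), seed = 3)
  expect_identical(s1$V1$values, s2$V1$values)
  expect_identical(s1$V5$values, s2$V5$values)
  r <- cor(as.vector(s1$V1$values), as.vector(s1$V2$values))
  expect_gte(abs(r), 0.85)
  # variables are standardised over the grid
  expect_equal(mean(s1$V3$values), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(s1$V3$values)), 1, tolerance = 1e-12)
  expect_error(make_env_stack(ex, 0.5, 3, corr_groups = list(c(1, 7))),
               "exceeds n_vars")
})

test_that("ungrouped variables stay below the correlation threshold", {
  ex <- c(30, 50, 45, 65)
  for (seed in 1:3) {
    s <- make_env_stack(ex, 0.5, 10, blur_cells = 2, seed = seed)
    m <- sapply(s, function(g) as.vector(g$values))
    cm <- cor(m)
    diag(cm) <- 0
    expect_lt(max(abs(cm)), 0.8)
  }
})

test_that("the logistic truth surface behaves as the formula dictates", {
  s <- make_env_stack(c(40, 45, 50, 55), 0.5, 3, seed = 5)
  flat <- true_suitability(s, c(V1 = 0), intercept = 0)
  expect_true(all(flat$values == 0.5))
  sat <- true_suitability(s, c(V1 = 0), intercept = -20)
  expect_lt(max(sat$values), 1e-8)
  mono <- true_suitability(s, c(V2 = 1), intercept = 0)
  expect_identical(order(as.vector(mono$values)), order(as.vector(s$V2$values)))
  expect_error(true_suitability(s, c(nope = 1)), "not in stack")
})

test_that("the accessibility field decays from its centres", {
  tmpl <- env_grid(matrix(0, 20, 20), 0, 0, 0.5)
  cc <- cell_centers(tmpl)
  centre <- data.frame(lon = cc$lon[210], lat = cc$lat[210])  # a cell centre
  b <- make_bias_field(tmpl, centre, decay_km = 50)
  expect_equal(b$values[cc$row[210], cc$col[210]], 1)          # exp(0)
  expect_true(all(b$values > 0))
  d <- haversine_km(cc$lon, cc$lat, centre$lon, centre$lat)
  w <- b$values[cbind(cc$row, cc$col)]
  expect_equal(w, exp(-d / 50), tolerance = 1e-12)             # exact kernel
  ord <- order(d)
  expect_true(all(diff(w[ord])[diff(d[ord]) > 1e-9] < 0))      # strictly monotone
  # two centres mirrored in longitude give a mirror-symmetric field
  b2 <- make_bias_field(tmpl, data.frame(lon = c(4, 6), lat = c(5, 5)), 30)
  expect_equal(b2$values, b2$values[, 20:1], tolerance = 1e-9)
  expect_error(make_bias_field(tmpl, centre, decay_km = 0), "decay_km")
})

test_that("presence sampling follows truth x bias and stays off masked cells", {
  tmpl <- matrix(0, 10, 10)
  tmpl[3, 4] <- 1
  truth <- env_grid(tmpl, 0, 0, 1)
  bias <- env_grid(matrix(1, 10, 10), 0, 0, 1)
  pts <- sample_presences(truth, bias, 50, seed = 2)
  expect_equal(nrow(pts), 50)
  expect_true(all(pts$lon >= 3 & pts$lon <= 4))     # col 4
  expect_true(all(pts$lat >= 7 & pts$lat <= 8))     # row 3 from the top
  expect_identical(nrow(sample_presences(truth, bias, 0)), 0L)
  expect_error(sample_presences(env_grid(matrix(0, 2, 2), 0, 0, 1),
                                env_grid(matrix(1, 2, 2), 0, 0, 1), 5),
               "sampling error")
  # masked cells never receive points
  vals <- matrix(runif(100), 10, 10)
  vals[, 1:5] <- NA
  tr2 <- env_grid(vals, 0, 0, 1)
  pts2 <- sample_presences(tr2, bias, 200, seed = 3)
  expect_true(all(pts2$lon >= 5))
  # law of large numbers: per-cell counts track truth x bias (a sharply
  # concentrated effort field keeps multinomial noise small per unit signal)
  w <- make_synthetic_world(seed = 4, n_presences = 0, bias_decay_km = 50)
  pts3 <- sample_presences(w$truth, w$bias, 5000, seed = 5)
  cell <- extract_values(w$stack, pts3)$cell
  counts <- matrix(0, 60, 60)
  for (k in seq_len(nrow(cell)))
    counts[cell$row[k], cell$col[k]] <- counts[cell$row[k], cell$col[k]] + 1
  expect_gt(cor(as.vector(counts), as.vector(w$truth$values * w$bias$values)),
            0.9)
})

test_that("sampling bias is recoverable from presence density", {
  w <- make_synthetic_world(seed = 6, n_presences = 0)
  pts <- sample_presences(w$truth, w$bias, 5000, seed = 7)
  cell <- extract_values(w$stack, pts)$cell
  counts <- matrix(0, 60, 60)
  for (k in seq_len(nrow(cell)))
    counts[cell$row[k], cell$col[k]] <- counts[cell$row[k], cell$col[k]] + 1
  use <- w$truth$values > 0.05
  expect_gt(cor((counts / w$truth$values)[use], w$bias$values[use]), 0.5)
})

test_that("the default world is reproducible and suppresses the cold strip", {
  w1 <- make_synthetic_world(seed = 9, n_presences = 100)
  w2 <- make_synthetic_world(seed = 9, n_presences = 100)
  expect_identical(w1$stack$BIO7$values, w2$stack$BIO7$values)
  expect_identical(w1$presences, w2$presences)
  expect_identical(w1$bias$values, w2$bias$values)
  cc <- cell_centers(w1$truth)
  strip <- matrix(cc$lat, 60, 60, byrow = TRUE) > 66
  expect_lt(mean(w1$truth$values[strip]), 0.02)
  expect_lt(max(w1$truth$values[strip]), 0.2)
  expect_true(all(w1$truth$values >= 0 & w1$truth$values <= 1))
})

test_that("future stacks shift only temperature-like variables, optionally by band", {
  w <- make_synthetic_world(seed = 10, n_presences = 0)
  fut <- make_future_stack(w$stack, warming = 1.5)
  expect_equal(fut$BIO1$values, w$stack$BIO1$values + 1.5)
  expect_identical(fut$BIO13$values, w$stack$BIO13$values)
  expect_identical(fut$SOC$values, w$stack$SOC$values)
  band <- make_future_stack(w$stack, warming = 2, lat_range = c(64, 70))
  cc <- cell_centers(w$stack[[1]])
  lat <- matrix(cc$lat, 60, 60, byrow = TRUE)
  expect_equal(band$BIO1$values[lat > 64], w$stack$BIO1$values[lat > 64] + 2)
  expect_identical(band$BIO1$values[lat < 64], w$stack$BIO1$values[lat < 64])
})

test_that("a world can be written to disk and read back", {
  w <- small_world(seed = 11, n_presences = 40)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  tr <- read_ascii_grid(file.path(dir, "truth.asc"))
  expect_equal(tr$values, w$truth$values, tolerance = 1e-6)
  b1 <- read_ascii_grid(file.path(dir, "BIO1.asc"))
  expect_equal(b1$values, w$stack$BIO1$values, tolerance = 1e-6)
  pres <- utils::read.csv(file.path(dir, "presences.csv"))
  expect_equal(pres$lon, w$presences$lon, tolerance = 1e-12)
})
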
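# Independent brute-force oracles used to check the implementation, plus
# small fixture builders. All oracles are deliberately naive (loops,
# exhaustive search) and share no code with the package internals.

# Pairwise ROC-AUC: loop over every presence/absence pair.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Exact maximum independent set size by branch and bound (n <= ~20).
bf_mis <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0L)
  rec <- function(rem) {
    if (!length(rem)) return(0L)
    v <- rem[1]
    nb <- rem[adj[v, rem]]
    if (!length(nb)) return(1L + rec(rem[-1]))            # v is free: take it
    max(1L + rec(setdiff(rem[-1], nb)), rec(rem[-1]))
  }
  rec(seq_len(n))
}

# Two-pass Pearson correlation matrix, element by element.
bf_pearson <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    a <- x[, i] - mean(x[, i]); b <- x[, j] - mean(x[, j])
    out[i, j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  out
}

# Containment-based point extraction: loop over every cell of every grid.
bf_extract <- function(stack, points) {
  g <- stack[[1]]
  cs <- g$cellsize
  ytop <- g$yllcorner + g$nrows * cs
  out <- matrix(NA_real_, nrow(points), length(stack),
                dimnames = list(NULL, names(stack)))
  for (k in seq_len(nrow(points))) {
    for (r in seq_len(g$nrows)) for (cc in seq_len(g$ncols)) {
      w <- g$xllcorner + (cc - 1) * cs
      n <- ytop - (r - 1) * cs
      if (points$lon[k] >= w && points$lon[k] < w + cs &&
          points$lat[k] <= n && points$lat[k] > n - cs) {
        for (v in seq_along(stack))
          out[k, v] <- stack[[v]]$values[r, cc]
      }
    }
  }
  out
}

# Band fractions and mean/max by an explicit cell loop.
bf_band_summary <- function(grid, low, high) {
  below <- mid <- above <- 0L; total <- 0L; s <- 0; mx <- -Inf
  for (r in seq_len(grid$nrows)) for (cc in seq_len(grid$ncols)) {
    v <- grid$values[r, cc]
    if (is.na(v)) next
    total <- total + 1L; s <- s + v; mx <- max(mx, v)
    if (v < low) below <- below + 1L
    else if (v > high) above <- above + 1L
    else mid <- mid + 1L
  }
  list(fraction_below_low = below / total, fraction_mid = mid / total,
       fraction_above_high = above / total, mean_suitability = s / total,
       max_suitability = mx)
}

# A small, fast synthetic world for unit tests (20 x 20 cells).
small_world <- function(seed = 1, n_presences = 300, ...) {
  make_synthetic_world(extent = c(40, 50, 50, 60), cellsize = 0.5,
                       n_presences = n_presences, cold_lat = 58,
                       n_centers = 8, seed = seed, ...)
}

# Random labelled scores, with optional heavy ties.
random_auc_instance <- function(n, tie_levels = NULL) {
  labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes
  scores <- stats::runif(n)
  if (!is.null(tie_levels))
    scores <- round(scores * tie_levels) / tie_levels
  list(scores = scores, labels = labels)
}
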
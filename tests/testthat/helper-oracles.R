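# Independent oracles, written as literal loop-based evaluations so they
# share no code path with the package implementation.

# Radial feature computed by looping over contour points exactly as the
# defining equations read: centroid mean, pointwise distances, arccos
# angle with the clockwise-sweep branch for x - xc < 0, ceiling bin
# index, per-bin summary, unit-sum normalization.
brute_force_feature <- function(contour, S, summary) {
  n <- nrow(contour)
  xc <- sum(contour[, 1]) / n
  yc <- sum(contour[, 2]) / n
  d <- numeric(n)
  alpha <- numeric(n)
  bin <- integer(n)
  for (i in seq_len(n)) {
    d[i] <- sqrt((contour[i, 1] - xc)^2 + (contour[i, 2] - yc)^2)
    if (d[i] == 0) { bin[i] <- 1L; next }
    arg <- (contour[i, 2] - yc) / d[i]
    arg <- min(1, max(-1, arg))
    a <- acos(arg) * 180 / pi
    alpha[i] <- if (contour[i, 1] - xc >= 0) a else 360 - a
    if (alpha[i] == 0) alpha[i] <- 360
    bin[i] <- as.integer(ceiling(S * alpha[i] / 360))
    if (bin[i] > S) bin[i] <- S
  }
  v <- numeric(S)
  for (j in seq_len(S)) {
    dj <- d[bin == j]
    if (length(dj) == 0) { v[j] <- 0; next }
    v[j] <- switch(summary,
      variance = { mu <- mean(dj); sum((dj - mu)^2) },
      max = max(dj),
      range = max(dj) - min(dj))
  }
  tot <- sum(v)
  if (tot <= 0) rep(0, S) else v / tot
}

# Random star-shaped polygon rasterized onto a small grid; guaranteed to
# contain a single connected foreground blob.
random_polygon_mask <- function(size = 48, n_harmonics = 3) {
  ctr <- (size + 1) / 2
  a <- runif(n_harmonics, 0, 0.25)
  ph <- runif(n_harmonics, 0, 2 * pi)
  r0 <- runif(1, 0.22, 0.34) * size
  xs <- matrix(rep(seq_len(size) - ctr, each = size), size)
  ys <- matrix(rep(seq_len(size) - ctr, times = size), size)
  theta <- atan2(ys, xs)
  r <- r0 * (1 + Reduce(`+`, lapply(seq_len(n_harmonics), function(k)
    a[k] * cos((k + 1) * theta + ph[k]))))
  sqrt(xs^2 + ys^2) <= r
}

# Minimum cost over every monotone warping path from (1,1) to (t,u),
# by explicit recursive enumeration (no memoization).
enumerate_dtw <- function(C) {
  t <- nrow(C); u <- ncol(C)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(C[1, 1])
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    best + C[i, j]
  }
  rec(t, u)
}

# Exact K-means on tiny inputs: exhaustive search over all assignments
# of n points to K clusters, returning the minimal total within-cluster
# sum of squares and its centers.
exact_kmeans <- function(x, K) {
  n <- nrow(x)
  stopifnot(K^n <= 1e6)
  best <- list(ss = Inf, centers = NULL)
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == K) {
      ss <- 0
      centers <- matrix(NA_real_, K, ncol(x))
      for (k in seq_len(K)) {
        pts <- x[assign == k, , drop = FALSE]
        centers[k, ] <- colMeans(pts)
        ss <- ss + sum(sweep(pts, 2, centers[k, ])^2)
      }
      if (ss < best$ss) best <- list(ss = ss, centers = centers)
    }
    i <- 1L
    while (i <= n && assign[i] == K) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# Sort rows lexicographically, for order-free center comparison.
sort_rows <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]

# Small feature-sequence training set with engineered nearest-neighbour
# structure (used by weight/assignment tests).
make_sequences <- function(frames_list, classes, views, actors = NULL,
                           ids = NULL) {
  n <- length(frames_list)
  if (is.null(actors)) actors <- rep("a1", n)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  lapply(seq_len(n), function(i)
    feature_sequence(frames_list[[i]], classes[i], views[i], actors[i], ids[i]))
}
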
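#' Parameters of the relevance-weighted sequence match
#'
#' Key poses with weight below `ambiguous_threshold` are considered
#' ambiguous, those above `discriminative_threshold` discriminative;
#' the thresholds drive the sign operator z of the relevance term (see
#' [select_z()]). With `use_relevance = FALSE` the pairwise cost falls
#' back to the plain Euclidean feature distance. `signed_relevance`
#' restores the literal signed deviation in the relevance magnitude
#' (by default the absolute deviation is used, so that z alone controls
#' the sign of the adjustment).
#'
#' @param ambiguous_threshold,discriminative_threshold Weight thresholds
#'   in `[0, 1]` with `ambiguous < discriminative`; defaults 0.1 and 0.9.
#' @param use_relevance Logical; apply the relevance adjustment.
#' @param signed_relevance Logical; use the signed deviation in the
#'   relevance magnitude instead of its absolute value.
#' @return An object of class `match_params`.
#' @export
match_params <- function(ambiguous_threshold = 0.1,
                         discriminative_threshold = 0.9,
                         use_relevance = TRUE,
                         signed_relevance = FALSE) {
  stopifnot(ambiguous_threshold >= 0,
            ambiguous_threshold < discriminative_threshold,
            discriminative_threshold <= 1)
  structure(list(ambiguous_threshold = ambiguous_threshold,
                 discriminative_threshold = discriminative_threshold,
                 use_relevance = isTRUE(use_relevance),
                 signed_relevance = isTRUE(signed_relevance)),
            class = "match_params")
}

#' Sign operator z of the relevance term
#'
#' Determines whether a key-pose pairing's relevance is subtracted
#' (z = -1, favoring the match) or added (z = +1, penalizing it):
#' two discriminative key poses follow the sign of the deviation
#' (below-average distances are favored, above-average penalized); two
#' ambiguous key poses are always favored; a discriminative/ambiguous
#' pairing is always penalized (such key poses should match partners of
#' similar weight); any other pairing follows the sign of the deviation.
#' A zero deviation is treated as "below average" (z = -1).
#'
#' @param w_i,w_j Key-pose weights in `[0, 1]` (vectorized).
#' @param dev Signed deviation of the Euclidean feature distance from the
#'   trained average distance.
#' @param params A [match_params()].
#' @return Integer vector of -1 / +1 values.
#' @export
select_z <- function(w_i, w_j, dev, params = match_params()) {
  disc_i <- w_i > params$discriminative_threshold
  disc_j <- w_j > params$discriminative_threshold
  amb_i <- w_i < params$ambiguous_threshold
  amb_j <- w_j < params$ambiguous_threshold
  z <- ifelse(dev > 0, 1L, -1L)            # default sign rule (dev = 0 -> -1)
  z[amb_i & amb_j] <- -1L                  # both ambiguous
  z[(disc_i & amb_j) | (amb_i & disc_j)] <- 1L  # mixed pairing
  z
}

#' Relevance-weighted distance between two key poses
#'
#' The Euclidean feature distance `e` is adjusted by the relevance of the
#' match: `rel = |e - average_distance| * w_i * w_j`, added or subtracted
#' according to [select_z()]. The result can be negative; it is not
#' clamped, since all matches are compared under the same scheme. With
#' `use_relevance = FALSE` the plain Euclidean distance is returned.
#'
#' @param feature_i,feature_j Key-pose feature vectors of equal length.
#' @param w_i,w_j The key poses' discriminative weights.
#' @param average_distance The bag's trained average match distance.
#' @param params A [match_params()].
#' @return A scalar distance (possibly negative when relevance is on).
#' @export
key_pose_distance <- function(feature_i, feature_j, w_i, w_j,
                              average_distance, params = match_params()) {
  if (length(feature_i) != length(feature_j))
    stop("key-pose features have mismatched lengths (",
         length(feature_i), " vs ", length(feature_j), ")")
  e <- sqrt(sum((feature_i - feature_j)^2))
  if (!params$use_relevance) return(e)
  dev <- e - average_distance
  mag <- if (params$signed_relevance) dev else abs(dev)
  z <- select_z(w_i, w_j, dev, params)
  e + z * mag * w_i * w_j
}

# Full pairwise key-pose cost matrix of a bag under given params.
# Both test and training sequences are sequences of bag members, so all
# DTW local costs are lookups into this matrix.
bag_cost_matrix <- function(bag, params = match_params()) {
  e <- as.matrix(stats::dist(bag$features))
  if (!params$use_relevance) return(e)
  dev <- e - bag$average_distance
  w_i <- matrix(bag$weight, nrow(e), ncol(e))
  w_j <- t(w_i)
  z <- select_z(w_i, w_j, dev, params)
  mag <- if (params$signed_relevance) dev else abs(dev)
  e + z * mag * w_i * w_j
}

#' Dynamic time warping distance between two key-pose sequences
#'
#' Classical unconstrained DTW: `dtw(i, j) = min(dtw(i-1, j),
#' dtw(i, j-1), dtw(i-1, j-1)) + cost(a_i, b_j)` with `dtw(0, 0) = 0` and
#' an infinite first row and column; no windowing, slope constraint or
#' path-length normalization. Costs may be negative (the relevance
#' adjustment can push pair costs below zero); the recursion is
#' unaffected.
#'
#' @param a,b [to_key_pose_sequence()] objects, or plain integer index
#'   vectors.
#' @param cost Either a matrix indexed by `[a_i, b_j]` (e.g.
#'   [key_pose_distance()] evaluated on all bag pairs) or a function
#'   `f(i, j)` returning the local cost of matching entry `i` of `a`
#'   with entry `j` of `b`.
#' @return The accumulated alignment distance `dtw(t, u)`.
#' @export
dtw_distance <- function(a, b, cost) {
  ai <- if (inherits(a, "key_pose_sequence")) a$indices else as.integer(a)
  bj <- if (inherits(b, "key_pose_sequence")) b$indices else as.integer(b)
  t <- length(ai); u <- length(bj)
  if (t == 0L || u == 0L) stop("DTW requires two non-empty sequences")
  local <- if (is.function(cost)) {
    outer(seq_len(t), seq_len(u), Vectorize(function(i, j) cost(ai[i], bj[j])))
  } else cost[ai, bj, drop = FALSE]
  dp <- matrix(Inf, t + 1L, u + 1L)
  dp[1L, 1L] <- 0
  for (i in seq_len(t)) {
    dpi <- dp[i, ]      # row i   (= dtw(i-1, .))
    dpn <- dp[i + 1L, ] # row i+1 (= dtw(i, .)) being filled
    li <- local[i, ]
    for (j in seq_len(u)) {
      dpn[j + 1L] <- min(dpi[j + 1L], dpn[j], dpi[j]) + li[j]
    }
    dp[i + 1L, ] <- dpn
  }
  dp[t + 1L, u + 1L]
}

#' Classify a multiview sequence with a trained key-pose model
#'
#' Each available test view's frames are rewritten as a sequence of key
#' poses and matched by DTW against every stored training key-pose
#' sequence (from all views: the view-specific key poses make same-view
#' matches naturally closer, so no hard view filter is applied). Per
#' view, the nearest training sequence is kept; the final label comes
#' from the view with the globally lowest distance (best-view fusion).
#' Ties are resolved toward the lowest training-sequence index, then the
#' first view.
#'
#' @param test_views Named list, one entry per available view: a
#'   [feature_sequence()] or a frames-by-S feature matrix.
#' @param model A [train_key_pose_model()] fit.
#' @param params A [match_params()].
#' @return An object of class `recognition_result` with
#'   `predicted_class`, `best_view`, `best_training_sequence_id`,
#'   `distance`, and `per_view` (a data frame of each view's best match).
#' @export
classify_sequence <- function(test_views, model, params = match_params()) {
  stopifnot(inherits(model, "key_pose_model"))
  if (length(test_views) == 0L) stop("no test views supplied")
  if (length(model$sequences) == 0L) stop("model holds no training sequences")
  if (is.null(names(test_views)) || any(!nzchar(names(test_views))))
    stop("test_views must be a named list (one entry per view)")
  cm <- bag_cost_matrix(model$bag, params)
  train_idx <- lapply(model$sequences, `[[`, "indices")
  train_cls <- vapply(model$sequences, `[[`, "", "action_class")
  train_ids <- vapply(model$sequences, `[[`, "", "sequence_id")

  per_view <- data.frame(view = names(test_views),
                         distance = NA_real_, label = NA_character_,
                         training_sequence_id = NA_character_,
                         stringsAsFactors = FALSE)
  best <- list(distance = Inf, view = NA_character_, class = NA_character_,
               id = NA_character_)
  for (v in seq_along(test_views)) {
    tv <- test_views[[v]]
    frames <- if (inherits(tv, "feature_sequence")) tv$frames else tv
    if (is.vector(frames)) frames <- matrix(frames, nrow = 1L)
    qi <- nn_bag(frames, model$bag$features)$index
    vbest_d <- Inf; vbest_k <- NA_integer_
    for (k in seq_along(train_idx)) {
      d <- dtw_distance(qi, train_idx[[k]], cm)
      if (d < vbest_d) { vbest_d <- d; vbest_k <- k }
    }
    per_view$distance[v] <- vbest_d
    per_view$label[v] <- train_cls[vbest_k]
    per_view$training_sequence_id[v] <- train_ids[vbest_k]
    if (vbest_d < best$distance) {
      best <- list(distance = vbest_d, view = per_view$view[v],
                   class = train_cls[vbest_k], id = train_ids[vbest_k])
    }
  }
  structure(list(predicted_class = best$class,
                 best_view = best$view,
                 best_training_sequence_id = best$id,
                 distance = best$distance,
                 per_view = per_view),
            class = "recognition_result")
}

#' @export
print.recognition_result <- function(x, ...) {
  cat("Predicted class:", x$predicted_class,
      "(best view:", x$best_view, ", distance:", format(x$distance), ")\n")
  invisible(x)
}
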
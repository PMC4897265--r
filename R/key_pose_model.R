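#' A labeled single-view sequence of pose features
#'
#' One camera stream of one action performance, as a frames-by-S matrix
#' of radial pose features plus its labels. Multiview performances are
#' represented as one `feature_sequence` per view sharing `sequence_id`.
#'
#' @param frames Numeric matrix, one row per frame, `S` columns.
#' @param action_class,view,actor Character labels.
#' @param sequence_id Identifier shared by all views of one performance.
#' @return An object of class `feature_sequence`.
#' @export
feature_sequence <- function(frames, action_class, view, actor = NA_character_,
                             sequence_id = NA_character_) {
  if (is.vector(frames)) frames <- matrix(frames, nrow = 1L)
  stopifnot(is.matrix(frames), nrow(frames) >= 1L)
  structure(list(frames = frames,
                 action_class = as.character(action_class),
                 view = as.character(view),
                 actor = as.character(actor),
                 sequence_id = as.character(sequence_id)),
            class = "feature_sequence")
}

# ---- seeded k-means++ clustering ------------------------------------------

# k-means++ initial centers; x has >= k distinct rows.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1L) for (i in 2:k) {
    prob <- d2
    prob[idx[seq_len(i - 1L)]] <- 0
    idx[i] <- if (sum(prob) <= 0) {
      cand <- setdiff(seq_len(n), idx[seq_len(i - 1L)])
      cand[sample.int(length(cand), 1L)]
    } else sample.int(n, 1L, prob = prob)
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[i], ], n, ncol(x), byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

# Seeded K-means: k-means++ initialization, Lloyd iterations, best of
# `nstart` restarts by total within-cluster sum of squares.
seeded_kmeans <- function(x, k, seed, nstart = 10L, iter_max = 100L) {
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) k <- n_distinct
  if (k == 1L) {
    return(list(centers = matrix(colMeans(x), 1L), k = 1L))
  }
  withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      # k <= number of distinct rows, so the ++ centers are distinct
      init <- kmeanspp_centers(x, k)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    list(centers = best$centers, k = k)
  })
}

# ---- bag of key poses ------------------------------------------------------

#' Learn the multiview bag of key poses
#'
#' For every combination of view and action class present in the training
#' set, K-means clustering (Euclidean distance, seeded k-means++
#' initialization, 10 restarts, best inertia kept) is run on that group's
#' pose features, and the `K` cluster centers become key poses labeled
#' with the group's view and class. The bag therefore holds `K * M * R`
#' key poses when every group has at least `K` frames; a group with fewer
#' frames contributes one key pose per distinct frame, with a warning.
#'
#' @param train List of [feature_sequence()] objects (all views, all
#'   classes).
#' @param K Number of key poses per (view, class) group.
#' @param seed Integer seed controlling the clustering initialization.
#' @param nstart Number of K-means restarts per group.
#' @return An object of class `bag_of_key_poses`: key-pose feature matrix
#'   with class/view labels, zeroed weight counters, and bookkeeping
#'   (`K`, `M`, `R`). Weights and `average_distance` are filled in by
#'   [compute_weights()] and [compute_average_distance()].
#' @export
learn_key_poses <- function(train, K, seed = 1L, nstart = 10L) {
  if (length(K) != 1L || is.na(K) || K < 1 || K != round(K))
    stop("K must be a positive integer")
  K <- as.integer(K)
  train <- check_training_set(train)
  # canonical order: clustering must not depend on how the caller
  # happened to store the sequences
  train <- train[order(vapply(train, `[[`, "", "view"),
                       vapply(train, `[[`, "", "action_class"),
                       vapply(train, `[[`, "", "actor"),
                       vapply(train, `[[`, "", "sequence_id"))]
  S <- ncol(train[[1L]]$frames)
  views <- sort(unique(vapply(train, `[[`, "", "view")))
  classes <- sort(unique(vapply(train, `[[`, "", "action_class")))
  feats <- list(); cls <- character(0); vw <- character(0)
  g <- 0L
  for (v in views) for (cl in classes) {
    sel <- Filter(function(s) s$view == v && s$action_class == cl, train)
    if (length(sel) == 0L) next
    g <- g + 1L
    x <- do.call(rbind, lapply(sel, `[[`, "frames"))
    k_eff <- min(K, nrow(x))
    if (k_eff < K)
      warning("group (view=", v, ", class=", cl, ") has ", nrow(x),
              " frames < K=", K, "; clamping K")
    fit <- seeded_kmeans(x, k_eff, seed = seed + g, nstart = nstart)
    feats[[g]] <- fit$centers
    cls <- c(cls, rep(cl, nrow(fit$centers)))
    vw <- c(vw, rep(v, nrow(fit$centers)))
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  structure(list(features = features,
                 action_class = cls,
                 view = vw,
                 weight = rep(0, nrow(features)),
                 matches = rep(0L, nrow(features)),
                 assignments = rep(0L, nrow(features)),
                 K = K, M = length(views), R = length(classes),
                 S = S,
                 views = views, classes = classes,
                 average_distance = NA_real_),
            class = "bag_of_key_poses")
}

#' @export
print.bag_of_key_poses <- function(x, ...) {
  cat("Bag of key poses:", nrow(x$features), "key poses (K =", x$K,
      ", M =", x$M, "views, R =", x$R, "classes, S =", x$S, ")\n")
  if (!is.na(x$average_distance))
    cat("  average_distance =", format(x$average_distance), "\n")
  invisible(x)
}

#' Nearest key pose of a feature vector
#'
#' Euclidean nearest neighbour in the bag; exact ties are broken by the
#' lowest key-pose index for determinism.
#'
#' @param x Numeric feature vector of length `bag$S` (or a matrix of such
#'   rows, in which case one match per row is returned).
#' @param bag A [learn_key_poses()] bag.
#' @return For a vector input, a list with `index`, `distance`,
#'   `action_class`, `view`, `weight`. For a matrix input, a list of
#'   vectors `index` and `distance`.
#' @export
nearest_key_pose <- function(x, bag) {
  stopifnot(inherits(bag, "bag_of_key_poses"))
  if (nrow(bag$features) == 0L) stop("empty bag of key poses")
  if (is.matrix(x)) {
    nn <- nn_bag(x, bag$features)
    return(list(index = nn$index, distance = nn$distance))
  }
  if (length(x) != bag$S)
    stop("feature length ", length(x), " does not match bag S = ", bag$S)
  nn <- nn_bag(matrix(x, 1L), bag$features)
  i <- nn$index[1L]
  list(index = i, distance = nn$distance[1L],
       action_class = bag$action_class[i], view = bag$view[i],
       weight = bag$weight[i])
}

# Vectorized nearest neighbour of rows of x among rows of centers.
# which.min returns the first minimum, i.e. the lowest index on ties.
nn_bag <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * tcrossprod(x, centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  d2[d2 < 0] <- 0
  idx <- max.col(-d2, ties.method = "first")
  list(index = idx, distance = sqrt(d2[cbind(seq_len(nrow(x)), idx)]))
}

#' Compute discriminative key-pose weights
#'
#' Every training frame is matched with its nearest key pose; for each
#' key pose, `assignments` counts how often it was chosen and `matches`
#' how often the matching frame came from the key pose's own action
#' class. The weight `w = matches / assignments` measures discriminative
#' power (1 = only matched within class, 0 = never within class); key
#' poses never selected keep `w = 0` but remain in the bag.
#'
#' @param bag A [learn_key_poses()] bag.
#' @param train The training set the bag was built from.
#' @return The bag with `weight`, `matches`, `assignments` filled in.
#' @export
compute_weights <- function(bag, train) {
  stopifnot(inherits(bag, "bag_of_key_poses"))
  train <- check_training_set(train)
  x <- do.call(rbind, lapply(train, `[[`, "frames"))
  frame_class <- unlist(lapply(train, function(s)
    rep(s$action_class, nrow(s$frames))))
  nn <- nn_bag(x, bag$features)
  B <- nrow(bag$features)
  bag$assignments <- tabulate(nn$index, B)
  within <- frame_class == bag$action_class[nn$index]
  bag$matches <- tabulate(nn$index[within], B)
  bag$weight <- ifelse(bag$assignments > 0L,
                       bag$matches / bag$assignments, 0)
  bag
}

#' Rewrite a feature sequence as a sequence of key poses
#'
#' Each frame is replaced by its nearest key pose in the bag, preserving
#' order and labels. This filters noise and outliers: frames map onto the
#' dictionary of known poses.
#'
#' @param seq A [feature_sequence()].
#' @param bag A [learn_key_poses()] bag.
#' @return An object of class `key_pose_sequence`: integer `indices` into
#'   the bag, the matching `distances`, and the sequence labels.
#' @export
to_key_pose_sequence <- function(seq, bag) {
  stopifnot(inherits(seq, "feature_sequence"),
            inherits(bag, "bag_of_key_poses"))
  if (nrow(seq$frames) == 0L) stop("empty sequence")
  nn <- nn_bag(seq$frames, bag$features)
  structure(list(indices = nn$index, distances = nn$distance,
                 action_class = seq$action_class, view = seq$view,
                 actor = seq$actor, sequence_id = seq$sequence_id),
            class = "key_pose_sequence")
}

#' Average training match distance of a bag
#'
#' The scalar against which feature-distance deviations are measured in
#' the relevance-weighted cost. Two readings are supported:
#' `"assignment"` (default) is the mean of the nearest-key-pose distances
#' recorded while converting all training frames; `"pairwise"` is the
#' mean pairwise Euclidean distance among the key poses themselves.
#'
#' @param bag A [learn_key_poses()] bag.
#' @param train Training set (required for `"assignment"`).
#' @param method `"assignment"` or `"pairwise"`.
#' @return A non-negative scalar.
#' @export
compute_average_distance <- function(bag, train = NULL,
                                     method = c("assignment", "pairwise")) {
  stopifnot(inherits(bag, "bag_of_key_poses"))
  method <- match.arg(method)
  if (method == "pairwise") {
    if (nrow(bag$features) < 2L) return(0)
    return(mean(stats::dist(bag$features)))
  }
  train <- check_training_set(train)
  x <- do.call(rbind, lapply(train, `[[`, "frames"))
  if (nrow(x) == 0L) stop("no training frames")
  mean(nn_bag(x, bag$features)$distance)
}

#' Train the full key-pose model
#'
#' Convenience pipeline: learn the bag ([learn_key_poses()]), compute the
#' discriminative weights ([compute_weights()]) and the average match
#' distance ([compute_average_distance()]), and convert every training
#' sequence to a key-pose sequence ([to_key_pose_sequence()]).
#'
#' @inheritParams learn_key_poses
#' @param average Reading of the average distance; see
#'   [compute_average_distance()].
#' @return An object of class `key_pose_model`: the trained `bag` and the
#'   list of training `sequences` (key-pose sequences).
#' @export
train_key_pose_model <- function(train, K, seed = 1L, nstart = 10L,
                                 average = c("assignment", "pairwise")) {
  average <- match.arg(average)
  train <- check_training_set(train)
  bag <- learn_key_poses(train, K, seed = seed, nstart = nstart)
  bag <- compute_weights(bag, train)
  bag$average_distance <- compute_average_distance(bag, train, method = average)
  sequences <- lapply(train, to_key_pose_sequence, bag = bag)
  structure(list(bag = bag, sequences = sequences),
            class = "key_pose_model")
}

#' @export
print.key_pose_model <- function(x, ...) {
  print(x$bag)
  cat("  training sequences:", length(x$sequences), "\n")
  invisible(x)
}

check_training_set <- function(train) {
  if (inherits(train, "feature_sequence")) train <- list(train)
  if (!is.list(train) || length(train) == 0L)
    stop("training set must be a non-empty list of feature sequences")
  if (!all(vapply(train, inherits, TRUE, "feature_sequence")))
    stop("training set must contain feature_sequence objects")
  S <- unique(vapply(train, function(s) ncol(s$frames), 0L))
  if (length(S) != 1L)
    stop("all training sequences must share one feature dimension S")
  train
}
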
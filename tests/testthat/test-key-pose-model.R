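test_that("a constant group collapses to a single key pose", {
  x <- c(0.2, 0.3, 0.5)
  train <- make_sequences(list(rbind(x, x, x, x)), "walk", "cam1")
  bag <- learn_key_poses(train, K = 1)
  expect_equal(nrow(bag$features), 1L)
  expect_equal(as.numeric(bag$features[1, ]), x)
  expect_equal(bag$action_class, "walk")
  expect_equal(bag$view, "cam1")
})

test_that("bag size is K per (view, class) group and K is clamped with warning", {
  withr::with_seed(5, {
    frames <- function() matrix(runif(40 * 6), 40)
    train <- list()
    for (v in c("cam1", "cam2")) for (cl in c("bend", "jump", "walk"))
      train <- c(train, make_sequences(list(frames()), cl, v,
                                       ids = paste0(v, cl)))
    bag <- learn_key_poses(train, K = 4)
    expect_equal(nrow(bag$features), 4 * 2 * 3)
    expect_equal(bag$M, 2L)
    expect_equal(bag$R, 3L)
    tab <- table(bag$view, bag$action_class)
    expect_true(all(tab == 4))
    # a group with fewer frames than K gets clamped
    tiny <- make_sequences(list(matrix(runif(2 * 6), 2)), "bend", "cam1")
    expect_warning(bag2 <- learn_key_poses(tiny, K = 5), "clamping")
    expect_equal(nrow(bag2$features), 2L)
  })
})

test_that("two well-separated clouds yield their exact means as centers", {
  withr::with_seed(8, {
    a <- matrix(rnorm(5 * 3, mean = 0, sd = 0.05), 5)
    b <- matrix(rnorm(6 * 3, mean = 5, sd = 0.05), 6)
    train <- make_sequences(list(rbind(a, b)), "act", "cam")
    bag <- learn_key_poses(train, K = 2, nstart = 10)
    got <- sort_rows(bag$features)
    # independent oracle: exhaustive exact 2-means over all partitions
    want <- sort_rows(exact_kmeans(rbind(a, b), 2)$centers)
    expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(sort_rows(rbind(colMeans(a), colMeans(b))), got,
                 tolerance = 1e-6, ignore_attr = TRUE)
  })
})

test_that("learned centers match exhaustive K-means on small groups", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      x <- matrix(runif(10 * 2), 10)
      train <- make_sequences(list(x), "act", "cam")
      bag <- learn_key_poses(train, K = 3, nstart = 25)
      want <- exact_kmeans(x, 3)
      ss <- sum(vapply(seq_len(nrow(x)), function(i)
        min(colSums((t(bag$features) - x[i, ])^2)), numeric(1)))
      expect_equal(ss, want$ss, tolerance = 1e-6)
      expect_equal(sort_rows(bag$features), sort_rows(want$centers),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  })
})

test_that("nearest key pose minimizes Euclidean distance with index ties", {
  bag <- learn_key_poses(
    make_sequences(list(rbind(c(0, 0), c(0, 0))), "a", "v"), K = 1)
  bag$features <- rbind(c(0, 0), c(1, 0), c(1, 0))
  bag$action_class <- c("a", "a", "a"); bag$view <- c("v", "v", "v")
  bag$weight <- c(0.5, 0.5, 0.5)
  hit <- nearest_key_pose(c(0, 0), bag)
  expect_equal(hit$index, 1L)
  expect_equal(hit$distance, 0)
  near <- nearest_key_pose(c(0.4, 0), bag)   # distances 0.4 and 0.6
  expect_equal(near$index, 1L)
  tie <- nearest_key_pose(c(0.5, 0), bag)    # exact tie -> lowest index
  expect_equal(tie$index, 1L)
  tie23 <- nearest_key_pose(c(2, 0), bag)    # tie between 2 and 3
  expect_equal(tie23$index, 2L)
})

test_that("weights are within-class match ratios (Algorithm 1 counters)", {
  # handcrafted bag: key poses at 0 and 10 on a line, classes A and B
  base <- make_sequences(list(matrix(c(0, 0), 1), matrix(c(10, 0), 1)),
                         c("A", "B"), c("v", "v"))
  bag <- learn_key_poses(base, K = 1)
  expect_equal(bag$action_class, c("A", "B"))
  # 4 frames match key pose 1 (3 of class A, 1 of class B); none match kp 2...
  # then one far B frame matches kp 2
  train <- make_sequences(
    list(rbind(c(0, 0), c(0.1, 0), c(-0.1, 0)),  # class A, all -> kp1
         rbind(c(0.2, 0)),                       # class B -> kp1
         rbind(c(10, 0))),                       # class B -> kp2
    c("A", "B", "B"), c("v", "v", "v"))
  bag <- compute_weights(bag, train)
  expect_equal(bag$assignments, c(4L, 1L))
  expect_equal(bag$matches, c(3L, 1L))
  expect_equal(bag$weight, c(0.75, 1))
  expect_equal(sum(bag$assignments), 5L)  # every frame assigned exactly once
})

test_that("unassigned key poses get weight 0; single-class training gives 1", {
  base <- make_sequences(list(matrix(c(0, 0), 1), matrix(c(10, 0), 1)),
                         c("A", "B"), c("v", "v"), ids = c("s1", "s2"))
  bag <- learn_key_poses(base, K = 1)
  # training contains only class A frames, all near the class-A key pose
  only_near <- make_sequences(list(rbind(c(0, 0), c(0.5, 0))), "A", "v")
  bag <- compute_weights(bag, only_near)
  expect_equal(bag$weight[bag$assignments == 0], 0)
  expect_true(all(bag$weight[bag$assignments > 0] == 1))
})

test_that("key-pose sequence conversion preserves length, labels, membership", {
  withr::with_seed(3, {
    centers <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
    train <- make_sequences(lapply(1:3, function(i)
      matrix(centers[i, ], 4, 3, byrow = TRUE)),
      c("a", "b", "c"), c("v", "v", "v"))
    bag <- learn_key_poses(train, K = 1)
    # idempotence: frames already equal to key poses map to themselves
    kps <- to_key_pose_sequence(train[[2]], bag)
    expect_length(kps$indices, 4L)
    expect_true(all(bag$features[kps$indices, 1] == 1))
    expect_equal(kps$action_class, "b")
    expect_equal(unique(kps$distances), 0)
    # 1-frame sequence -> 1-entry sequence
    one <- feature_sequence(matrix(c(0, 0, 1), 1), "a", "v")
    expect_length(to_key_pose_sequence(one, bag)$indices, 1L)
    # small perturbations below half the inter-center gap keep the match
    noisy <- feature_sequence(
      matrix(centers[1, ], 20, 3, byrow = TRUE) + matrix(rnorm(60, 0, 0.05), 20),
      "a", "v")
    expect_true(all(to_key_pose_sequence(noisy, bag)$indices ==
                      to_key_pose_sequence(noisy, bag)$indices[1]))
  })
})

test_that("average distance is the mean nearest-match distance", {
  base <- make_sequences(list(matrix(c(0, 0), 1), matrix(c(100, 0), 1)),
                         c("A", "B"), c("v", "v"))
  bag <- learn_key_poses(base, K = 1)
  # frames at distances 1 and 3 from their nearest key poses
  train <- make_sequences(list(matrix(c(1, 0), 1), matrix(c(97, 0), 1)),
                          c("A", "B"), c("v", "v"))
  expect_equal(compute_average_distance(bag, train), 2)
  # exact matches -> 0
  expect_equal(compute_average_distance(bag, base), 0)
  # duplicating the dataset leaves the mean unchanged
  expect_equal(compute_average_distance(bag, c(train, train)), 2)
  # pairwise reading: distance between the two key poses
  expect_equal(compute_average_distance(bag, method = "pairwise"), 100)
})

test_that("trained model carries weights, average distance and sequences", {
  withr::with_seed(13, {
    train <- list()
    for (cl in c("a", "b")) for (i in 1:2)
      train <- c(train, make_sequences(
        list(matrix(runif(10 * 4), 10) + ifelse(cl == "a", 0, 2)),
        cl, "v", "act1", paste0(cl, i)))
    model <- train_key_pose_model(train, K = 2, seed = 1)
    expect_s3_class(model, "key_pose_model")
    expect_length(model$sequences, 4L)
    expect_true(all(model$bag$weight >= 0 & model$bag$weight <= 1))
    expect_equal(sum(model$bag$assignments), 40L)
    expect_gt(model$bag$average_distance, 0)
    expect_true(all(unlist(lapply(model$sequences, `[[`, "indices")) <=
                      nrow(model$bag$features)))
  })
})

test_that("model serialization round-trips", {
  withr::with_seed(17, {
    train <- list()
    for (cl in c("a", "b")) for (v in c("v1", "v2"))
      train <- c(train, make_sequences(list(matrix(runif(24), 6)), cl, v,
                                       "act1", paste0(cl, v)))
    model <- train_key_pose_model(train, K = 2, seed = 3)
    path <- withr::local_tempfile(fileext = ".json")
    save_key_pose_model(model, path, config = radial_feature_config(4, "max"))
    back <- load_key_pose_model(path)
    expect_identical(back$bag$action_class, model$bag$action_class)
    expect_identical(back$bag$view, model$bag$view)
    expect_identical(back$bag$matches, model$bag$matches)
    expect_identical(back$bag$assignments, model$bag$assignments)
    expect_identical(lapply(back$sequences, `[[`, "indices"),
                     lapply(model$sequences, `[[`, "indices"))
    expect_equal(back$bag$features, model$bag$features,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(back$bag$weight, model$bag$weight, tolerance = 1e-12)
    expect_equal(back$bag$average_distance, model$bag$average_distance,
                 tolerance = 1e-12)
    expect_equal(attr(back, "config")$S, 4L)
    expect_equal(attr(back, "config")$summary, "max")
  })
})
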
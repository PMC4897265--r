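#' Configuration of the synthetic multiview silhouette generator
#'
#' The generator emulates the input regime of multiview silhouette
#' action datasets: several action classes with distinct shape dynamics,
#' several actors with consistent per-actor shape variation, multiple
#' synchronized camera views, and optional boundary noise mimicking
#' segmentation errors. The dataset is a pure function of the
#' configuration (including `seed`).
#'
#' @param classes Number of action classes R.
#' @param views Number of camera views M.
#' @param actors Number of actors.
#' @param sequences_per_actor Performances per actor and class.
#' @param frames_per_sequence Frames per view stream.
#' @param image_size Side length of the square frames, pixels.
#' @param actor_scale_jitter Relative range of the per-actor
#'   multiplicative perturbation of shape parameters (0 = identical
#'   actors).
#' @param boundary_noise Independent flip probability, in `[0, 0.5)`,
#'   applied to pixels in a 1-pixel band around the true contour.
#' @param seed Integer master seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(classes = 3L, views = 2L, actors = 3L,
                         sequences_per_actor = 2L, frames_per_sequence = 20L,
                         image_size = 80L, actor_scale_jitter = 0,
                         boundary_noise = 0, seed = 1L) {
  counts <- c(classes, views, actors, sequences_per_actor,
              frames_per_sequence, image_size)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be positive integers")
  if (boundary_noise < 0 || boundary_noise >= 0.5)
    stop("boundary_noise must lie in [0, 0.5)")
  if (actor_scale_jitter < 0 || actor_scale_jitter >= 1)
    stop("actor_scale_jitter must lie in [0, 1)")
  structure(list(classes = as.integer(classes), views = as.integer(views),
                 actors = as.integer(actors),
                 sequences_per_actor = as.integer(sequences_per_actor),
                 frames_per_sequence = as.integer(frames_per_sequence),
                 image_size = as.integer(image_size),
                 actor_scale_jitter = actor_scale_jitter,
                 boundary_noise = boundary_noise,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Shape family of a class: a star-shaped radius profile r(theta) whose
# lobe count is class-specific (disjoint families) and whose lobe
# amplitude and orientation oscillate smoothly with the motion phase.
class_shape_params <- function(class_id) {
  # low lobe counts stay below the Nyquist limit of typical bin counts
  # (S ~ 12), so distinct classes cannot alias onto each other
  lobes <- c(2L, 3L, 4L, 5L, 6L, 7L)[((class_id - 1L) %% 6L) + 1L]
  list(lobes = lobes,
       amp = 0.22,
       elong = 0.06,
       elong_dir = pi * (class_id - 1L) / 3)
}

#' Render one synthetic silhouette frame
#'
#' Draws a filled star-shaped polygon (limb-like lobes around a convex
#' core) whose lobe amplitude and orientation vary smoothly with `phase`;
#' each class uses a distinct lobe count, and each view applies a fixed
#' affine deformation (rotation plus anisotropic squash) to the shape.
#' Star-shaped regions are single connected components by construction.
#'
#' @param class_id,view_id Positive integers.
#' @param phase Motion phase in `[0, 1)`.
#' @param scale Relative size of the figure (> 0).
#' @param size Image side length, pixels (>= 8).
#' @param shape_jitter Optional per-actor perturbation, a list with
#'   multipliers `amp`, `base` and additive angle `dir` (as drawn by
#'   [generate_dataset()]).
#' @return A logical mask of dimension `size x size`.
#' @export
render_pose <- function(class_id, view_id, phase, scale = 1, size = 64L,
                        shape_jitter = NULL) {
  if (class_id < 1 || view_id < 1) stop("class_id and view_id must be >= 1")
  if (scale <= 0) stop("scale must be positive")
  size <- as.integer(size)
  if (size < 8L) stop("degenerate image size: ", size)
  p <- class_shape_params(as.integer(class_id))
  amp_mult <- base_mult <- 1; dir_add <- 0
  if (!is.null(shape_jitter)) {
    amp_mult <- shape_jitter$amp; base_mult <- shape_jitter$base
    dir_add <- shape_jitter$dir
  }
  # lobe amplitude breathes with phase; the lobes barely rotate, so the
  # class's bin pattern stays put while frames still evolve visibly
  amp <- p$amp * (0.75 + 0.25 * cos(2 * pi * phase)) * amp_mult
  lobe_rot <- 0.05 * sin(2 * pi * phase) + dir_add
  # 0.17 leaves headroom: the radius never exceeds size/2 for scale <= 2
  r0 <- 0.17 * size * scale * base_mult

  # fixed per-view affine deformation: rotate then squash y
  rot <- (view_id - 1L) * pi / 7
  squash <- 1 / (1 + 0.30 * (view_id - 1L))
  ctr <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size) - ctr, each = size), size)   # cols = x
  ys <- matrix(rep(seq_len(size) - ctr, times = size), size)  # rows = y
  # invert the view transform on pixel offsets before the radius test
  ys2 <- ys / squash
  xr <- cos(rot) * xs + sin(rot) * ys2
  yr <- -sin(rot) * xs + cos(rot) * ys2
  theta <- atan2(yr, xr)
  rad <- sqrt(xr^2 + yr^2)
  rfun <- r0 * (1 + amp * cos(p$lobes * (theta - lobe_rot)) +
                  p$elong * cos(2 * (theta - p$elong_dir - dir_add)))
  rad <= rfun
}

#' Generate a deterministic multiview silhouette action dataset
#'
#' Produces `classes * actors * sequences_per_actor` multiview
#' sequences, each holding `views` synchronized streams of
#' `frames_per_sequence` masks. Actor identity perturbs the shape
#' parameters once per actor (consistently across that actor's
#' sequences), so leave-one-actor-out evaluation genuinely tests
#' unseen-actor generalization; sequences differ by a random phase
#' offset. Optional boundary noise flips pixels in a 1-pixel band around
#' the contour.
#'
#' @param config A [synth_config()].
#' @return An object of class `silhouette_dataset`: `config` plus a list
#'   `sequences`, each with `action_class`, `actor`, `sequence_id` and a
#'   named list `views` of mask lists.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    jit <- config$actor_scale_jitter
    actor_jitter <- lapply(seq_len(config$actors), function(a)
      list(amp = 1 + runif(1, -jit, jit),
           base = 1 + runif(1, -jit, jit),
           dir = runif(1, -jit, jit)))
    sequences <- list()
    for (cl in seq_len(config$classes))
      for (a in seq_len(config$actors))
        for (sq in seq_len(config$sequences_per_actor)) {
          offset <- runif(1, 0, 0.25)
          phases <- (offset + (seq_len(config$frames_per_sequence) - 1) /
                       config$frames_per_sequence) %% 1
          views <- list()
          for (v in seq_len(config$views)) {
            frames <- lapply(phases, function(ph) {
              m <- render_pose(cl, v, ph, scale = 1, size = config$image_size,
                               shape_jitter = actor_jitter[[a]])
              if (config$boundary_noise > 0)
                m <- flip_boundary_band(m, config$boundary_noise)
              m
            })
            views[[paste0("view", v)]] <- frames
          }
          sequences[[length(sequences) + 1L]] <-
            list(action_class = paste0("class", cl),
                 actor = paste0("actor", a),
                 sequence_id = sprintf("class%d_actor%d_seq%d", cl, a, sq),
                 views = views)
        }
    structure(list(config = config, sequences = sequences),
              class = "silhouette_dataset")
  })
}

# Flip pixels independently within the 1-pixel band around the contour
# (foreground pixels 4-adjacent to background and vice versa), mimicking
# segmentation errors.
flip_boundary_band <- function(mask, prob) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- mask
  up <- pad[1:n, 2:(m + 1L)]; down <- pad[3:(n + 2L), 2:(m + 1L)]
  left <- pad[2:(n + 1L), 1:m]; right <- pad[2:(n + 1L), 3:(m + 2L)]
  any4 <- up | down | left | right
  all4 <- up & down & left & right
  band <- (mask & !all4) | (!mask & any4)
  flips <- band & (matrix(runif(n * m), n) < prob)
  xor(mask, flips)
}

#' @export
print.silhouette_dataset <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic silhouette dataset:", length(x$sequences),
      "multiview sequences (", cfg$classes, "classes x", cfg$actors,
      "actors x", cfg$sequences_per_actor, "sequences;", cfg$views,
      "views x", cfg$frames_per_sequence, "frames of",
      cfg$image_size, "x", cfg$image_size, "px)\n")
  invisible(x)
}
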
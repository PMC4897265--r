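MODEL_FORMAT_VERSION <- "1.0"

#' Save a trained key-pose model to JSON
#'
#' Writes a single versioned JSON file holding the feature configuration,
#' the key-pose features, labels, weights and counters, the trained
#' average distance, and the converted training key-pose sequences (as
#' indices into the bag). Reals are written at full precision, so a
#' round trip is exact for labels and indices and within 1e-12 for
#' floating-point values.
#'
#' @param model A [train_key_pose_model()] fit.
#' @param path Output file path.
#' @param config Optional [radial_feature_config()] to store alongside
#'   the model (so a loaded model knows how to featurize new frames).
#' @return `path`, invisibly.
#' @export
save_key_pose_model <- function(model, path, config = NULL) {
  stopifnot(inherits(model, "key_pose_model"))
  bag <- model$bag
  obj <- list(
    format = "keyposes-model",
    version = MODEL_FORMAT_VERSION,
    config = if (!is.null(config))
      list(S = config$S, summary = config$summary)
    else list(S = bag$S),
    K = bag$K, M = bag$M, R = bag$R, S = bag$S,
    views = bag$views, classes = bag$classes,
    key_poses = list(
      features = unname(bag$features),
      action_class = bag$action_class,
      view = bag$view,
      weight = bag$weight,
      matches = bag$matches,
      assignments = bag$assignments
    ),
    average_distance = bag$average_distance,
    sequences = lapply(model$sequences, function(s)
      list(indices = s$indices, action_class = s$action_class,
           view = s$view, actor = s$actor, sequence_id = s$sequence_id))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Load a key-pose model saved by [save_key_pose_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `key_pose_model`; the stored feature configuration (if any)
#'   is attached as attribute `"config"`.
#' @export
load_key_pose_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "keyposes-model"))
    stop("not a keyposes model file: ", path)
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stop("unsupported model format version ", obj$version)
  kp <- obj$key_poses
  chr <- function(x) vapply(x, as.character, "")
  num <- function(x) vapply(x, as.numeric, 0)
  features <- do.call(rbind, lapply(kp$features, num))
  bag <- structure(list(
    features = features,
    action_class = chr(kp$action_class),
    view = chr(kp$view),
    weight = num(kp$weight),
    matches = as.integer(num(kp$matches)),
    assignments = as.integer(num(kp$assignments)),
    K = as.integer(obj$K), M = as.integer(obj$M), R = as.integer(obj$R),
    S = as.integer(obj$S),
    views = chr(obj$views), classes = chr(obj$classes),
    average_distance = as.numeric(obj$average_distance)
  ), class = "bag_of_key_poses")
  sequences <- lapply(obj$sequences, function(s) {
    structure(list(indices = as.integer(num(s$indices)),
                   distances = NULL,
                   action_class = as.character(s$action_class),
                   view = as.character(s$view),
                   actor = as.character(s$actor),
                   sequence_id = as.character(s$sequence_id)),
              class = "key_pose_sequence")
  })
  model <- structure(list(bag = bag, sequences = sequences),
                     class = "key_pose_model")
  summ <- obj$config$summary
  if (is.character(summ) && length(summ) == 1L)
    attr(model, "config") <- radial_feature_config(obj$config$S, summ)
  model
}
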
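#' Write a silhouette dataset to the standard directory layout
#'
#' Layout: `<root>/<class>/<actor>/<sequence>/<view>/frame_00001.png`,
#' plus a `manifest.json` at the root listing classes, actors, views,
#' sequences and (for synthetic data) the generator configuration.
#'
#' @param dataset A [generate_dataset()] result (or any object of class
#'   `silhouette_dataset`).
#' @param dir Output root directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "silhouette_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in dataset$sequences) {
    for (v in names(s$views)) {
      d <- file.path(dir, s$action_class, s$actor, s$sequence_id, v)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      frames <- s$views[[v]]
      for (i in seq_along(frames))
        write_mask(frames[[i]], file.path(d, sprintf("frame_%05d.png", i)))
    }
  }
  manifest <- list(
    format = "keyposes-dataset", version = "1.0",
    classes = sort(unique(vapply(dataset$sequences, `[[`, "", "action_class"))),
    actors = sort(unique(vapply(dataset$sequences, `[[`, "", "actor"))),
    views = names(dataset$sequences[[1L]]$views),
    sequences = lapply(dataset$sequences, function(s)
      list(action_class = s$action_class, actor = s$actor,
           sequence_id = s$sequence_id)),
    config = if (!is.null(dataset$config)) unclass(dataset$config)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a silhouette dataset from the standard directory layout
#'
#' Reads the layout written by [write_dataset()]. If no `manifest.json`
#' is present the directory tree is walked directly
#' (`<class>/<actor>/<sequence>/<view>/*.png|pgm`, frames in
#' lexicographic order).
#'
#' @param dir Dataset root directory.
#' @return A `silhouette_dataset`.
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("dataset directory not found: ", dir)
  sequences <- list()
  for (cl in sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))) {
    for (a in sort(list.dirs(file.path(dir, cl), recursive = FALSE,
                             full.names = FALSE))) {
      for (sq in sort(list.dirs(file.path(dir, cl, a), recursive = FALSE,
                                full.names = FALSE))) {
        views <- list()
        for (v in sort(list.dirs(file.path(dir, cl, a, sq),
                                 recursive = FALSE, full.names = FALSE))) {
          files <- sort(list.files(file.path(dir, cl, a, sq, v),
                                   pattern = "\\.(png|pgm|ppm)$",
                                   full.names = TRUE, ignore.case = TRUE))
          if (length(files) == 0L) next
          views[[v]] <- lapply(files, read_mask)
        }
        if (length(views) > 0L)
          sequences[[length(sequences) + 1L]] <-
            list(action_class = cl, actor = a, sequence_id = sq,
                 views = views)
      }
    }
  }
  if (length(sequences) == 0L) stop("no sequences found under ", dir)
  cfg <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf, simplifyVector = TRUE)
    if (!is.null(man$config)) cfg <- man$config
  }
  structure(list(config = cfg, sequences = sequences),
            class = "silhouette_dataset")
}

#' Extract pose features for every frame of a dataset
#'
#' Runs [pose_feature()] on each mask once, so that evaluation folds can
#' reuse the features. Sequences keep their labels; each view stream
#' becomes a frames-by-S feature matrix.
#'
#' @param dataset A `silhouette_dataset`.
#' @param config A [radial_feature_config()].
#' @return An object of class `feature_dataset` (same sequence
#'   structure, feature matrices instead of mask lists).
#' @export
dataset_features <- function(dataset, config = radial_feature_config()) {
  stopifnot(inherits(dataset, "silhouette_dataset"))
  sequences <- lapply(dataset$sequences, function(s) {
    feats <- lapply(names(s$views), function(v) {
      frames <- s$views[[v]]
      do.call(rbind, lapply(seq_along(frames), function(i)
        as.numeric(pose_feature(frames[[i]], config,
                                frame = paste0(s$sequence_id, "/", v,
                                               "/frame", i)))))
    })
    names(feats) <- names(s$views)
    list(action_class = s$action_class, actor = s$actor,
         sequence_id = s$sequence_id, views = feats)
  })
  structure(list(config = config, sequences = sequences),
            class = "feature_dataset")
}
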
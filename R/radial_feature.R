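#' Configuration of the radial pose feature
#'
#' @param S Number of equal-angle radial bins about the contour centroid.
#'   Typical values are 8-46; 12 is a good default for coarse silhouettes.
#' @param summary Per-bin summary of the centroid distances: `"range"`
#'   (max minus min; the most robust overall), `"max"`, or `"variance"`
#'   (sum of squared deviations from the bin mean).
#' @return An object of class `radial_feature_config`.
#' @export
radial_feature_config <- function(S = 12L, summary = c("range", "max", "variance")) {
  structure(list(S = check_bins(S), summary = match.arg(summary)),
            class = "radial_feature_config")
}

#' @export
print.radial_feature_config <- function(x, ...) {
  cat("Radial feature config: S =", x$S, ", summary =", x$summary, "\n")
  invisible(x)
}

#' Radial pose feature of a silhouette
#'
#' Reduces one binary silhouette to an `S`-dimensional descriptor:
#' contour points are grouped into `S` equal-angle bins about the contour
#' centroid, each bin's centroid distances are collapsed to one summary
#' value, and the `S` summaries are normalized to unit sum (which makes
#' the feature scale invariant; it is translation invariant by
#' construction). If every bin summarizes to zero (e.g. a perfect circle
#' under the range summary) the all-zero vector is returned with the
#' `degenerate` attribute set, so downstream Euclidean distances stay
#' well defined.
#'
#' @param mask A logical or 0/1 numeric matrix (rows = y, columns = x).
#' @param config A [radial_feature_config()].
#' @param frame Optional label used in error messages to identify the
#'   offending frame.
#' @return Numeric vector of length `config$S` with attribute
#'   `degenerate` (logical scalar). Non-degenerate features are
#'   non-negative and sum to 1.
#' @seealso [pose_feature_from_contour()] to start from an already
#'   extracted contour.
#' @export
pose_feature <- function(mask, config = radial_feature_config(), frame = NULL) {
  contour <- extract_contour(mask)
  pose_feature_from_contour(contour, config, frame = frame)
}

#' Radial pose feature of an extracted contour
#'
#' @param contour A two-column `(x, y)` matrix with at least 3 points.
#' @inheritParams pose_feature
#' @return See [pose_feature()].
#' @export
pose_feature_from_contour <- function(contour, config = radial_feature_config(),
                                      frame = NULL) {
  stopifnot(inherits(config, "radial_feature_config"))
  contour <- check_contour(contour)
  if (nrow(contour) < 3L)
    stop("unusable contour (", nrow(contour), " < 3 points)",
         if (!is.null(frame)) paste0(" in frame ", frame))
  # translate to the bounding-box origin: integer pixel contours then
  # produce bit-identical features under any integer mask offset
  contour[, 1L] <- contour[, 1L] - min(contour[, 1L])
  contour[, 2L] <- contour[, 2L] - min(contour[, 2L])
  center <- contour_centroid(contour)
  d <- centroid_distances(contour, center)
  bins <- bin_assignment(contour, center, config$S)
  v <- vapply(seq_len(config$S), function(j)
    summarize_bin(d[bins == j], config$summary), numeric(1))
  total <- sum(v)
  # rounding noise (e.g. the ranges of a rasterized perfect circle) must
  # count as zero mass: threshold relative to the contour radius
  if (total <= 1e-9 * max(d, 1))
    return(structure(rep(0, config$S), degenerate = TRUE))
  structure(v / total, degenerate = FALSE)
}

#' Is a pose feature degenerate?
#'
#' @param x A feature returned by [pose_feature()].
#' @return `TRUE` when the pre-normalization bin summaries summed to zero.
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))
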
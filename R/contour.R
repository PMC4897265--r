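#' Extract the ordered outer contour of a silhouette
#'
#' Labels the foreground with 4-connected components, keeps the largest
#' component (a warning is emitted when specks are discarded) and traces
#' its outer boundary with the classic border-following algorithm
#' (via [EBImage::ocontour()]). The traversal direction is normalized so
#' that repeated calls on congruent shapes return the same orientation;
#' on 1-pixel-wide protrusions the trace revisits pixels, as border
#' following does.
#'
#' @param mask A logical or 0/1 numeric matrix (rows = y, columns = x).
#' @return A numeric matrix with columns `x`, `y`: the boundary pixels of
#'   the largest foreground component in traversal order (1-based pixel
#'   coordinates).
#' @export
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
#' extract_contour(m)
extract_contour <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask)) stop("no silhouette: mask has no foreground pixels")
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(round(lab)), nrow = nrow(mask))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  if (length(sizes) > 1L)
    warning("mask has ", length(sizes),
            " foreground components; using the largest (",
            sizes[keep], " px)")
  comp <- matrix(0L, nrow(mask), ncol(mask))
  comp[lab == keep] <- 1L
  oc <- EBImage::ocontour(comp)[[1L]]
  # ocontour returns 0-based (row, col) = (y-1, x-1) along the traversal
  pts <- cbind(x = oc[, 2L] + 1, y = oc[, 1L] + 1)
  normalize_orientation(pts)
}

# Fix one traversal direction via the shoelace signed area (ties and
# degenerate n <= 2 contours are left as traced).
normalize_orientation <- function(pts) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  x <- pts[, 1L]; y <- pts[, 2L]
  nxt <- c(2:n, 1L)
  area2 <- sum(x * y[nxt] - x[nxt] * y)
  if (area2 < 0) pts <- pts[n:1, , drop = FALSE]
  pts
}

#' Centroid of a contour
#'
#' Arithmetic mean of the contour point coordinates; real-valued, not
#' rounded to the pixel grid.
#'
#' @param contour A two-column `(x, y)` matrix as returned by
#'   [extract_contour()].
#' @return Named numeric vector `c(x = , y = )`.
#' @export
contour_centroid <- function(contour) {
  contour <- check_contour(contour)
  c(x = mean(contour[, 1L]), y = mean(contour[, 2L]))
}

#' Distances from contour points to a center
#'
#' @param contour A two-column `(x, y)` matrix.
#' @param center Numeric `(x, y)` pair, usually [contour_centroid()].
#' @return Numeric vector of Euclidean distances, one per contour point,
#'   in contour order.
#' @export
centroid_distances <- function(contour, center = contour_centroid(contour)) {
  contour <- check_contour(contour)
  sqrt((contour[, 1L] - center[[1L]])^2 + (contour[, 2L] - center[[2L]])^2)
}

#' Assign contour points to equal-angle radial bins
#'
#' The angle of each point about the center is measured as a clockwise
#' sweep in image coordinates (y growing downward), starting from the
#' downward vertical: alpha = arccos((y - y_c)/d) for x - x_c >= 0 and
#' 360 - arccos((y - y_c)/d) otherwise, with alpha = 0 mapped to 360.
#' Bin `ceiling(S * alpha / 360)` is assigned, so an angle exactly on a
#' bin boundary belongs to the lower-index bin. A point coincident with
#' the center (d = 0) falls in bin 1 by convention.
#'
#' @param contour A two-column `(x, y)` matrix.
#' @param center Numeric `(x, y)` pair.
#' @param S Number of radial bins (>= 1).
#' @return Integer vector of bin indices in `1:S`, one per contour point.
#' @export
bin_assignment <- function(contour, center = contour_centroid(contour), S) {
  contour <- check_contour(contour)
  S <- check_bins(S)
  dx <- contour[, 1L] - center[[1L]]
  dy <- contour[, 2L] - center[[2L]]
  d <- sqrt(dx^2 + dy^2)
  alpha <- (atan2(dx, dy) * 180 / pi) %% 360
  alpha[alpha == 0] <- 360
  s <- as.integer(ceiling(S * alpha / 360))
  s[s > S] <- S  # guard against rounding just above a full turn
  s[d == 0] <- 1L
  s
}

#' Summarize the centroid distances of one radial bin
#'
#' Three summaries are supported: `"variance"` is the sum of squared
#' deviations from the bin mean (no division by the count), `"max"` the
#' largest distance and `"range"` the difference between largest and
#' smallest. An empty bin summarizes to 0.
#'
#' @param distances Numeric vector of centroid distances (possibly empty).
#' @param summary One of `"variance"`, `"max"`, `"range"`.
#' @return A single non-negative number.
#' @export
summarize_bin <- function(distances, summary = c("variance", "max", "range")) {
  summary <- match.arg(summary)
  if (length(distances) == 0L) return(0)
  switch(summary,
         variance = sum((distances - mean(distances))^2),
         max = max(distances),
         range = max(distances) - min(distances))
}

check_contour <- function(contour) {
  if (is.data.frame(contour)) contour <- as.matrix(contour)
  if (!is.matrix(contour) || ncol(contour) != 2L || nrow(contour) < 1L)
    stop("contour must be a non-empty two-column (x, y) matrix")
  storage.mode(contour) <- "double"
  contour
}

check_bins <- function(S) {
  if (length(S) != 1L || is.na(S) || S < 1 || S != round(S))
    stop("S must be a positive integer")
  as.integer(S)
}
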
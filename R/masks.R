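#' Coerce an object to a binary silhouette mask
#'
#' A mask is a logical matrix: rows index image y (growing downward),
#' columns index x. Numeric matrices are thresholded at zero, so any
#' nonzero pixel counts as foreground.
#'
#' @param x A logical or numeric matrix.
#' @return A logical matrix.
#' @export
as_binary_mask <- function(x) {
  if (!is.matrix(x)) stop("a binary mask must be a matrix")
  if (is.logical(x)) return(x)
  if (!is.numeric(x)) stop("a binary mask must be logical or numeric")
  x != 0
}

#' Read a silhouette mask from a PNG or PGM file
#'
#' PNG files are read with the png package (the first channel is used);
#' PGM files (formats P2 and P5) are parsed directly. Any nonzero pixel is
#' foreground.
#'
#' @param path Path to a `.png`, `.pgm` or `.ppm` file.
#' @return A logical matrix (rows = y, columns = x).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img != 0)
  }
  if (ext %in% c("pgm", "ppm")) return(read_pgm(path) != 0)
  stop("unsupported mask format: ", path)
}

#' Write a silhouette mask to a PNG file
#'
#' @param mask A logical or 0/1 numeric matrix.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

# Minimal PGM reader (P2 ascii / P5 binary, maxval <= 255).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens: magic, width, height, maxval (comments start with '#')
  while (length(tokens) < 4L) {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated PGM header: ", path)
    line <- sub("#.*$", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
    tokens <- tokens[nzchar(tokens)]
  }
  magic <- tokens[1L]
  w <- as.integer(tokens[2L])
  h <- as.integer(tokens[3L])
  maxval <- as.integer(tokens[4L])
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stop("invalid PGM dimensions in ", path)
  if (magic == "P5") {
    if (maxval > 255L) stop("16-bit PGM not supported: ", path)
    vals <- as.integer(readBin(con, "raw", n = w * h))
    if (length(vals) < w * h) stop("truncated PGM data: ", path)
  } else if (magic == "P2") {
    rest <- readLines(con, warn = FALSE)
    rest <- sub("#.*$", "", rest)
    vals <- as.integer(unlist(strsplit(trimws(rest), "\\s+")))
    vals <- vals[!is.na(vals)]
    if (length(vals) < w * h) stop("truncated PGM data: ", path)
    vals <- vals[seq_len(w * h)]
  } else stop("unsupported PGM magic '", magic, "' in ", path)
  # PGM is stored row-major (rows = y), matching the mask convention
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
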
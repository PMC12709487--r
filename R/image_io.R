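#' Image containers
#'
#' Lightweight S3 containers for the three raster types the analyses run
#' on: `rgb_image` (height x width x 3 array, intensities 0--255),
#' `gray_image` (height x width matrix, real-valued intensities 0--255)
#' and `binary_image` (logical foreground mask plus the threshold fraction
#' that produced it).
#'
#' @param pixels numeric array/matrix of intensities in `[0, 255]`, or a
#'   logical matrix for `binary_image`.
#' @param source_path optional file the pixels were read from.
#' @param threshold_fraction fraction of the 0--255 dynamic range used to
#'   binarize (recorded, may be `NA` for masks not born from a threshold).
#' @return An object of the corresponding class.
#' @name image-classes
NULL

#' @rdname image-classes
#' @export
rgb_image <- function(pixels, source_path = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("rgb_image needs a height x width x 3 array")
  if (any(pixels < 0 | pixels > 255)) stopf("channel values must lie in [0, 255]")
  structure(list(pixels = pixels, source_path = source_path), class = "rgb_image")
}

#' @rdname image-classes
#' @export
gray_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stopf("gray_image needs a numeric matrix")
  if (any(pixels < 0 | pixels > 255)) stopf("intensities must lie in [0, 255]")
  structure(list(pixels = pixels), class = "gray_image")
}

#' @rdname image-classes
#' @export
binary_image <- function(pixels, threshold_fraction = NA_real_) {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) stopf("binary_image needs a logical matrix")
  structure(list(pixels = pixels, threshold_fraction = threshold_fraction),
            class = "binary_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %d x %d, source: %s>\n", d[1], d[2],
              ifelse(is.na(x$source_path), "<memory>", x$source_path)))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%.1f, %.1f]>\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image %d x %d, %.1f%% foreground, threshold %s>\n",
              nrow(x$pixels), ncol(x$pixels), 100 * mean(x$pixels),
              format(x$threshold_fraction)))
  invisible(x)
}

#' Read a PNG or TIFF image
#'
#' Reads 8- or 16-bit PNG/TIFF files; intensities are rescaled to the
#' 0--255 range.  Grayscale files are promoted to three identical
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return An [rgb_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '.%s' (PNG or TIFF expected)", ext))
  # readPNG/readTIFF return values in [0, 1] regardless of bit depth
  px <- raw * 255
  if (length(dim(px)) == 2L) {
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  } else if (dim(px)[3] >= 3L) {
    px <- px[, , 1:3, drop = FALSE]
  } else if (dim(px)[3] == 2L) {         # gray + alpha
    px <- array(rep(px[, , 1L], 3L), dim = c(dim(px)[1:2], 3L))
  } else {
    px <- array(rep(px[, , 1L], 3L), dim = c(dim(px)[1:2], 3L))
  }
  rgb_image(px, source_path = path)
}

#' Convert to grayscale by ITU-R luminance weighting
#'
#' `gray = 0.299 R + 0.587 G + 0.114 B`, the standard luminance
#' combination; values remain in `[0, 255]`.
#'
#' @param img an [rgb_image()].
#' @return A [gray_image()].
#' @export
to_grayscale <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  p <- img$pixels
  gray_image(0.299 * p[, , 1L] + 0.587 * p[, , 2L] + 0.114 * p[, , 3L])
}

#' Extract one color channel as a grayscale plane
#'
#' The red channel is the conventional input for the IPR analysis; any of
#' the three channels can be pulled out unmodified.
#'
#' @param img an [rgb_image()].
#' @param channel `"red"`, `"green"`, `"blue"` or an integer 1--3.
#' @return A [gray_image()].
#' @export
extract_channel <- function(img, channel = "red") {
  stopifnot(inherits(img, "rgb_image"))
  if (is.character(channel))
    channel <- match(match.arg(channel, c("red", "green", "blue")),
                     c("red", "green", "blue"))
  if (!channel %in% 1:3) stopf("channel must be 'red', 'green', 'blue' or 1..3")
  gray_image(img$pixels[, , channel])
}

#' Resize a grayscale image to the standard analysis side
#'
#' Bilinear interpolation to a `side x side` raster (default 512, a power
#' of two so that all dyadic block partitions divide evenly).  Values are
#' clipped to `[0, 255]`.
#'
#' @param img a [gray_image()].
#' @param side target side in pixels; a positive power of two.
#' @return A [gray_image()] of dimension `side x side`.
#' @export
resize_to_standard <- function(img, side = 512L) {
  stopifnot(inherits(img, "gray_image"))
  side <- as.integer(side)
  if (side < 1L || bitwAnd(side, side - 1L) != 0L)
    stopf("side must be a positive power of two, got %d", side)
  p <- img$pixels
  if (nrow(p) == side && ncol(p) == side) return(img)
  out <- EBImage::resize(p, w = side, h = side, filter = "bilinear")
  gray_image(clip255(as.matrix(out)))
}

#' Threshold a grayscale image into a foreground mask
#'
#' The cut value is `threshold_fraction * 255` (a fraction of the full
#' dynamic range, not of the per-image maximum).  By default foreground is
#' the *dark* phase -- pixels strictly below the cut -- because in
#' transmission imaging optically dense, mass-rich tissue absorbs light
#' and appears dark.  `invert = TRUE` selects the bright phase (pixels at
#' or above the cut) instead.
#'
#' @param img a [gray_image()].
#' @param threshold_fraction fraction of the dynamic range in `[0, 1]`.
#' @param invert take the bright phase as foreground.
#' @return A [binary_image()] recording `threshold_fraction`.
#' @export
binarize <- function(img, threshold_fraction, invert = FALSE) {
  stopifnot(inherits(img, "gray_image"))
  if (!is.numeric(threshold_fraction) || threshold_fraction < 0 || threshold_fraction > 1)
    stopf("threshold_fraction must lie in [0, 1]")
  cut <- threshold_fraction * 255
  fg <- if (invert) img$pixels >= cut else img$pixels < cut
  binary_image(fg, threshold_fraction = threshold_fraction)
}

#' Partition an image into non-overlapping square blocks
#'
#' Returns the `(side / block_side)^2` sub-boxes of the image in row-major
#' order, each carrying its `(block_row, block_col)` grid position
#' (1-based).  A 512 x 512 image with `block_side = 32` yields the
#' standard 16 x 16 = 256 sub-boxes.
#'
#' @param x a [gray_image()] or [binary_image()].
#' @param block_side block side in pixels; must divide the image side.
#' @return A list of blocks of the same class as `x`.
#' @export
partition <- function(x, block_side) {
  UseMethod("partition")
}

partition_matrix <- function(p, block_side, wrap) {
  nr <- nrow(p); nc <- ncol(p)
  block_side <- as.integer(block_side)
  if (block_side < 1L || nr %% block_side != 0L || nc %% block_side != 0L)
    stopf("block_side %d does not divide the image dimensions %d x %d",
          block_side, nr, nc)
  gr <- nr %/% block_side; gc <- nc %/% block_side
  out <- vector("list", gr * gc)
  k <- 0L
  for (r in seq_len(gr)) {
    rows <- ((r - 1L) * block_side + 1L):(r * block_side)
    for (cc in seq_len(gc)) {
      cols <- ((cc - 1L) * block_side + 1L):(cc * block_side)
      k <- k + 1L
      b <- wrap(p[rows, cols, drop = FALSE])
      b$block_row <- r
      b$block_col <- cc
      out[[k]] <- b
    }
  }
  out
}

#' @export
partition.gray_image <- function(x, block_side) {
  partition_matrix(x$pixels, block_side, gray_image)
}

#' @export
partition.binary_image <- function(x, block_side) {
  tf <- x$threshold_fraction
  partition_matrix(x$pixels, block_side, function(m) binary_image(m, tf))
}
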
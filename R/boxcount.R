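#' Box-count a binary block over a set of grid scales
#'
#' Covers the block with grids of cell size `eps` and counts, for each
#' scale, the cells containing at least one foreground pixel.
#'
#' @param block a [binary_image()] (any square side).
#' @param scales integer vector of box sides `eps`; each must divide the
#'   block side.
#' @return A `boxcount_curve`: list with `scales`, `counts` (N(eps)) and
#'   the block's grid coordinate if it has one.
#' @export
box_count <- function(block, scales) {
  stopifnot(inherits(block, "binary_image"))
  m <- block$pixels
  side <- nrow(m)
  scales <- as.integer(sort(scales))
  if (any(scales < 1L) || any(side %% scales != 0L))
    stopf("every scale must divide the block side %d", side)
  counts <- vapply(scales, function(e) {
    s <- rowsum(m + 0, rep(seq_len(side %/% e), each = e))
    s <- t(rowsum(t(s), rep(seq_len(side %/% e), each = e)))
    sum(s > 0)
  }, integer(1))
  structure(list(scales = scales, counts = counts,
                 block_coord = c(block$block_row, block$block_col)),
            class = "boxcount_curve")
}

#' Fractal dimension from a box-count curve
#'
#' Ordinary least-squares slope of `ln N(eps)` against `ln(1/eps)`, using
#' only scales with `N(eps) > 0`; the slope is the box-counting dimension.
#' Clipped to `[0, 2]` to guard against floating-point noise.  Blocks with
#' fewer than two usable scales are degenerate and yield `NA`.
#'
#' @param curve a `boxcount_curve` from [box_count()].
#' @return The fractal dimension, or `NA_real_` for a degenerate block.
#' @export
fit_dimension <- function(curve) {
  stopifnot(inherits(curve, "boxcount_curve"))
  ok <- curve$counts > 0
  if (sum(ok) < 2L) return(NA_real_)
  x <- log(1 / curve$scales[ok])
  y <- log(curve$counts[ok])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  min(max(slope, 0), 2)
}

# dyadic scales 2 .. block_side/2; the full-block scale (N = 1 always)
# carries no information and is excluded from the fit
default_scales <- function(block_side) {
  if (block_side < 4L) stopf("block_side must be at least 4 for a two-scale fit")
  2^seq(1L, floor(log2(block_side)) - 1L)
}

#' Per-sub-box fractal dimension map
#'
#' Partitions a binary image into `block_side`-sided sub-boxes and fits a
#' box-counting dimension in each, producing the fractal map (16 x 16 =
#' 256 values for a 512 image at block 32).  Empty or degenerate blocks
#' are `NA` and excluded from the map mean and standard deviation.
#'
#' @param img a [binary_image()] (square, side divisible by `block_side`).
#' @param block_side sub-box side in pixels (default 32).
#' @param scales box-count scales; default dyadic `2 .. block_side/2`.
#' @param keep_curves retain the underlying box-count curves.
#' @return A `fractal_map`: list with `df` (matrix of dimensions, `NA` for
#'   degenerate blocks), `block_side`, `threshold_fraction`, `mean`, `std`
#'   (population convention, defined entries only) and optionally `curves`.
#' @export
fractal_map <- function(img, block_side = 32L, scales = NULL,
                        keep_curves = FALSE) {
  stopifnot(inherits(img, "binary_image"))
  if (is.null(scales)) scales <- default_scales(block_side)
  blocks <- partition(img, block_side)
  g <- as.integer(sqrt(length(blocks)))
  df <- matrix(NA_real_, g, g)
  curves <- if (keep_curves) vector("list", length(blocks)) else NULL
  for (i in seq_along(blocks)) {
    cv <- box_count(blocks[[i]], scales)
    df[blocks[[i]]$block_row, blocks[[i]]$block_col] <- fit_dimension(cv)
    if (keep_curves) curves[[i]] <- cv
  }
  structure(list(df = df, block_side = block_side,
                 threshold_fraction = img$threshold_fraction,
                 scales = scales,
                 mean = mean(df[is.finite(df)]),
                 std = pop_sd(df),
                 curves = curves),
            class = "fractal_map")
}

#' @export
print.fractal_map <- function(x, ...) {
  cat(sprintf("<fractal_map %d x %d blocks (side %d), mean Df %.4f, STD %.4f, %d degenerate>\n",
              nrow(x$df), ncol(x$df), x$block_side, x$mean, x$std,
              sum(!is.finite(x$df))))
  invisible(x)
}

# pooled per-group mean/std of sub-box dimensions for one parameter value
pool_df_stats <- function(values, labels, parameter, value) {
  do.call(rbind, lapply(unique(labels), function(g) {
    v <- unlist(values[labels == g])
    v <- v[is.finite(v)]
    data.frame(parameter = parameter, value = value, group = g,
               mean = if (length(v)) mean(v) else NA_real_,
               std = pop_sd(v), n = length(v))
  }))
}

#' Length-scale sweep of the fractal dimension
#'
#' Recomputes the pooled sub-box dimension statistics of each group at a
#' series of block sides (the whole-image side gives one value per image),
#' tracing how mean and spread of Df respond to the analysis scale.
#'
#' @param images list of [gray_image()]s.
#' @param labels group label per image (two groups typical).
#' @param block_sides block sides to sweep (must divide the image side).
#' @param threshold_fraction binarization threshold (default 0.65).
#' @param invert passed to [binarize()].
#' @return A `sweep_table` data.frame: `parameter`, `value`, `group`,
#'   `mean`, `std`, `n`.
#' @export
sweep_length_scale <- function(images, labels,
                               block_sides = c(32L, 64L, 128L, 256L, 512L),
                               threshold_fraction = 0.65, invert = FALSE) {
  check_cohort(images, labels)
  bins <- lapply(images, binarize, threshold_fraction = threshold_fraction,
                 invert = invert)
  out <- do.call(rbind, lapply(block_sides, function(b) {
    vals <- lapply(bins, function(bi) fractal_map(bi, block_side = b)$df)
    pool_df_stats(vals, labels, "length_scale", b)
  }))
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Threshold sweep of the fractal dimension
#'
#' Pooled per-group Df statistics across a ladder of binarization
#' fractions.  Also reports, as attributes `best_mean_gap_fraction` and
#' `best_std_gap_fraction`, the fraction maximizing the absolute
#' between-group gap in the mean and in the standard deviation.
#'
#' @param images list of [gray_image()]s.
#' @param labels group label per image (exactly two groups for the gap
#'   attributes).
#' @param fractions threshold fractions in `[0, 1]`.
#' @param block_side sub-box side (default 32).
#' @param invert passed to [binarize()].
#' @return A `sweep_table` data.frame (see [sweep_length_scale()]).
#' @export
sweep_threshold <- function(images, labels, fractions, block_side = 32L,
                            invert = FALSE) {
  check_cohort(images, labels)
  if (length(fractions) == 0L) stopf("at least one threshold fraction is required")
  out <- do.call(rbind, lapply(fractions, function(f) {
    vals <- lapply(images, function(im)
      fractal_map(binarize(im, f, invert = invert), block_side = block_side)$df)
    pool_df_stats(vals, labels, "threshold", f)
  }))
  groups <- unique(labels)
  if (length(groups) == 2L) {
    gap <- function(col) vapply(fractions, function(f) {
      a <- out[out$value == f & out$group == groups[1], col]
      b <- out[out$value == f & out$group == groups[2], col]
      abs(b - a)
    }, numeric(1))
    attr(out, "best_mean_gap_fraction") <- fractions[which.max(gap("mean"))]
    attr(out, "best_std_gap_fraction") <- fractions[which.max(gap("std"))]
  }
  class(out) <- c("sweep_table", "data.frame")
  out
}

check_cohort <- function(images, labels) {
  if (length(images) == 0L) stopf("empty image set")
  if (length(labels) != length(images))
    stopf("labels must match images (%d vs %d)", length(labels), length(images))
  if (any(table(labels) == 0L)) stopf("empty group")
  invisible(TRUE)
}
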
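#' Normalized box measure of a grayscale image
#'
#' Coarse-grains the intensity raster onto boxes of side `eps` and
#' normalizes to a probability measure: `P_i` = (intensity mass in box i)
#' / (total image intensity).
#'
#' @param img a [gray_image()] with positive total intensity.
#' @param eps box side; must divide the image side.
#' @return Matrix of box probabilities summing to 1.
#' @export
normalized_measure <- function(img, eps) {
  stopifnot(inherits(img, "gray_image"))
  p <- img$pixels
  side <- nrow(p)
  eps <- as.integer(eps)
  if (eps < 1L || side %% eps != 0L) stopf("eps must divide the image side %d", side)
  tot <- sum(p)
  if (tot <= 0) stopf("image has zero total intensity")
  s <- rowsum(p, rep(seq_len(side %/% eps), each = eps))
  s <- t(rowsum(t(s), rep(seq_len(side %/% eps), each = eps)))
  dimnames(s) <- NULL
  s / tot
}

#' q-weighted Chhabra-Jensen measures
#'
#' `mu_i(q) = P_i^q / sum_j P_j^q`, computed in log space so that large
#' `|q|` and tiny probabilities do not overflow.  Zero-probability boxes
#' must be removed beforehand.
#'
#' @param p vector of positive box probabilities (summing to 1).
#' @param q moment order.
#' @return Vector `mu` summing to 1.
#' @export
chhabra_weights <- function(p, q) {
  if (any(p <= 0)) stopf("probabilities must be strictly positive (drop empty boxes)")
  lw <- q * log(p)
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Chhabra-Jensen multifractal spectrum
#'
#' Direct estimation of the singularity spectrum: for each moment order q
#' the Hoelder exponent `alpha(q)` is the regression slope over scales of
#' `sum_i mu_i ln P_i` against `ln eps`, and `f(q)` the slope of
#' `sum_i mu_i ln mu_i` against `ln eps`, with `mu_i = P_i^q / sum P_j^q`.
#' No Legendre transform is involved; `tau(q) = q alpha(q) - f(q)`.
#' Zero-intensity boxes are dropped before weighting.  Per-q regression
#' R-squared values (the smaller of the alpha- and f-regressions) are
#' recorded as fit diagnostics.
#'
#' Exact identities hold by construction: `tau(1) = 0` and
#' `f(alpha(1)) = alpha(1)` (at q = 1 the two regressions coincide).
#'
#' @param img a [gray_image()].
#' @param q_grid moment orders (default -10 to 10 in steps of 0.5).
#' @param scales box sides (>= 3, each dividing the image side; default
#'   dyadic 8..128 for a 512 image).
#' @return A `mf_spectrum`: `q`, `alpha`, `f_alpha`, `tau`, `r2`,
#'   `scales`.
#' @export
mf_spectrum <- function(img, q_grid = seq(-10, 10, by = 0.5),
                        scales = c(8L, 16L, 32L, 64L, 128L)) {
  stopifnot(inherits(img, "gray_image"))
  scales <- as.integer(sort(scales))
  if (length(scales) < 3L) stopf("at least 3 scales are required")
  le <- log(scales)
  # per scale: vectors of ln P over non-empty boxes
  lp_list <- lapply(scales, function(e) {
    P <- as.vector(normalized_measure(img, e))
    log(P[P > 0])
  })
  nq <- length(q_grid)
  A <- matrix(NA_real_, nq, length(scales))  # sum mu ln P
  Fm <- matrix(NA_real_, nq, length(scales))  # sum mu ln mu
  for (s in seq_along(scales)) {
    lp <- lp_list[[s]]
    for (k in seq_len(nq)) {
      q <- q_grid[k]
      lw <- q * lp
      lw <- lw - max(lw)
      w <- exp(lw)
      mu <- w / sum(w)
      lmu <- lw - log(sum(w))
      A[k, s] <- sum(mu * lp)
      Fm[k, s] <- sum(mu * lmu)
    }
  }
  slope_r2 <- function(y) {
    sx <- le - mean(le)
    b <- sum(sx * (y - mean(y))) / sum(sx^2)
    fit <- mean(y) + b * sx
    ss <- sum((y - fit)^2); st <- sum((y - mean(y))^2)
    c(b, if (st == 0) 1 else 1 - ss / st)
  }
  al <- t(apply(A, 1, slope_r2))
  fl <- t(apply(Fm, 1, slope_r2))
  structure(list(q = q_grid, alpha = al[, 1], f_alpha = fl[, 1],
                 tau = q_grid * al[, 1] - fl[, 1],
                 r2 = pmin(al[, 2], fl[, 2]), scales = scales),
            class = "mf_spectrum")
}

#' @export
print.mf_spectrum <- function(x, ...) {
  m <- spectrum_metrics(x)
  cat(sprintf("<mf_spectrum over q [%g, %g]: width %.4f, peak alpha %.4f, asymmetry %+.4f>\n",
              min(x$q), max(x$q), m$width, m$peak_alpha, m$asymmetry))
  invisible(x)
}

#' Width, peak and asymmetry of a multifractal spectrum
#'
#' `width = alpha_max - alpha_min`; `peak_alpha` is the Hoelder exponent
#' at the spectrum maximum (q = 0 for a proper spectrum); the signed
#' asymmetry `(alpha_max - peak) - (peak - alpha_min)` is positive when
#' the spectrum extends further toward weak singularities (high alpha).
#'
#' @param s a `mf_spectrum`.
#' @return A one-row data.frame: `width`, `peak_alpha`, `asymmetry`.
#' @export
spectrum_metrics <- function(s) {
  stopifnot(inherits(s, "mf_spectrum"))
  a_min <- min(s$alpha); a_max <- max(s$alpha)
  peak <- s$alpha[which.max(s$f_alpha)]
  data.frame(width = a_max - a_min, peak_alpha = peak,
             asymmetry = (a_max - peak) - (peak - a_min))
}
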
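#' Sierpinski carpet
#'
#' Deterministic level-`k` carpet on a `3^k`-sided grid: each level keeps
#' the 8 outer cells of a 3 x 3 subdivision, so the foreground count is
#' `8^k` and the box-counting dimension is `ln 8 / ln 3 = 1.8928`, an
#' exact oracle for the dimension estimator.
#'
#' @param levels recursion depth (>= 1).
#' @return A [binary_image()] of side `3^levels`.
#' @export
sierpinski_carpet <- function(levels) {
  stopifnot(levels >= 1)
  pat <- matrix(1, 3, 3); pat[2, 2] <- 0
  m <- Reduce(function(a, b) kronecker(a, b), rep(list(pat), levels))
  binary_image(m > 0)
}

#' Vicsek cross fractal
#'
#' Level-`k` plus-sign fractal (the 5 cross cells of a 3 x 3 subdivision);
#' dimension `ln 5 / ln 3 = 1.4650`.  A second deterministic oracle for
#' the box-counting estimator.
#'
#' @param levels recursion depth (>= 1).
#' @return A [binary_image()] of side `3^levels`.
#' @export
vicsek_cross <- function(levels) {
  stopifnot(levels >= 1)
  pat <- matrix(0, 3, 3); pat[2, ] <- 1; pat[, 2] <- 1
  m <- Reduce(function(a, b) kronecker(a, b), rep(list(pat), levels))
  binary_image(m > 0)
}

# the 24 permutations of 4 child slots, one row each
perm4 <- local({
  g <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  g[apply(g, 1, function(r) length(unique(r)) == 4L), , drop = FALSE]
})

#' Randomized multiplicative cascade measure
#'
#' Recursive quadrant mass splitting: at every level each cell's mass is
#' divided among its four children according to `weights`, with the
#' weight-to-quadrant assignment shuffled independently per cell (so the
#' field looks tissue-like while the multiset of box masses -- and hence
#' the multifractal spectrum -- is exactly that of the deterministic
#' cascade).  Total mass 1 is conserved at every level.
#'
#' @param weights four non-negative quadrant weights summing to 1.
#' @param levels recursion depth; output side is `2^levels`.
#' @param seed RNG seed for the per-cell shuffles (optional).
#' @return A list: `image` (a [gray_image()] with the measure linearly
#'   rescaled to a 0--255 maximum, real-valued), `measure` (the exact
#'   probability masses, summing to 1), `weights`, `levels`.
#' @export
multiplicative_cascade <- function(weights, levels, seed = NULL) {
  if (length(weights) != 4L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12)
    stopf("weights must be 4 non-negative values summing to 1")
  stopifnot(levels >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(1, 1, 1)
  for (l in seq_len(levels)) {
    n <- nrow(m)
    pid <- sample.int(nrow(perm4), n * n, replace = TRUE)
    cw <- matrix(weights[perm4[pid, ]], n * n, 4L)   # cells column-major
    new <- matrix(0, 2L * n, 2L * n)
    odd <- seq(1L, 2L * n, by = 2L); even <- odd + 1L
    new[odd, odd]   <- m * matrix(cw[, 1], n, n)
    new[odd, even]  <- m * matrix(cw[, 2], n, n)
    new[even, odd]  <- m * matrix(cw[, 3], n, n)
    new[even, even] <- m * matrix(cw[, 4], n, n)
    m <- new
  }
  list(image = gray_image(m / max(m) * 255), measure = m,
       weights = weights, levels = levels)
}

#' Closed-form multifractal spectrum of a quadrant cascade
#'
#' For a cascade with quadrant weights `p_i` (dyadic subdivision):
#' `tau(q) = -log2(sum p_i^q)`,
#' `alpha(q) = -sum p_i^q ln p_i / (ln 2 * sum p_i^q)`,
#' `f(q) = q alpha(q) - tau(q)`.  The analytic oracle the Chhabra-Jensen
#' estimator is validated against.
#'
#' @param weights four positive weights summing to 1.
#' @param q_grid moment orders.
#' @return A data.frame: `q`, `tau`, `alpha`, `f`.
#' @export
analytic_cascade_spectrum <- function(weights, q_grid = seq(-10, 10, by = 0.5)) {
  if (any(weights <= 0)) stopf("analytic spectrum needs strictly positive weights")
  s_q <- vapply(q_grid, function(q) sum(weights^q), numeric(1))
  d_q <- vapply(q_grid, function(q) sum(weights^q * log(weights)), numeric(1))
  tau <- -log2(s_q)
  alpha <- -d_q / (log(2) * s_q)
  data.frame(q = q_grid, tau = tau, alpha = alpha, f = q_grid * alpha - tau)
}

#' Correlated Gaussian disorder field
#'
#' Stationary Gaussian random field with exponential spatial correlation
#' `exp(-r / lc)`, sampled by circulant (spectral) synthesis on the torus,
#' rescaled to a zero-mean fluctuation of *relative* standard deviation
#' `dn` around `base_intensity`:
#' `I = base_intensity * (1 + g)`, clipped to `[0, 255]`.
#' `dn = 0` returns the exactly uniform image.
#'
#' @param side image side in pixels.
#' @param dn relative fluctuation strength (standard deviation of
#'   `dI / I0`), >= 0.
#' @param lc correlation length in pixels (>= 1).
#' @param base_intensity mean intensity (default 170).
#' @param seed RNG seed (optional).
#' @return A [gray_image()]; the generating parameters are attached as
#'   attribute `params`.
#' @export
disorder_field <- function(side, dn, lc, base_intensity = 170, seed = NULL) {
  stopifnot(side >= 2, dn >= 0, lc >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (dn == 0) {
    img <- gray_image(matrix(base_intensity, side, side))
  } else {
    g <- gauss_field_exp(side, lc)
    g <- (g - mean(g)) / stats::sd(g) * dn
    img <- gray_image(clip255(base_intensity * (1 + g)))
  }
  attr(img, "params") <- list(side = side, dn = dn, lc = lc,
                              base_intensity = base_intensity)
  img
}

# circulant sampling of a field with target correlation exp(-d/lc) on the
# torus; negative spectral weights (embedding error) are floored at zero.
# absolute scale is irrelevant: callers rescale to the target sd.
gauss_field_exp <- function(side, lc) {
  ix <- 0:(side - 1L)
  d <- pmin(ix, side - ix)
  D <- sqrt(outer(d^2, d^2, "+"))
  S <- Re(stats::fft(exp(-D / lc)))
  S[S < 0] <- 0
  W <- matrix(stats::rnorm(side^2), side) + 1i * matrix(stats::rnorm(side^2), side)
  Re(stats::fft(sqrt(S) * W, inverse = TRUE)) / side^2
}

#' Default cohort presets
#'
#' Generating parameters for the two synthetic cohorts: the disease
#' preset has stronger intensity fluctuations (`dn`), a longer disorder
#' correlation length (`lc`) and more heterogeneous cascade weights than
#' the control preset -- the directionally correct synthetic analog of
#' dense, disordered tissue.  These presets are synthetic study
#' conditions, not measurements of any real tissue.
#'
#' @return A named list: `dn`, `lc`, `weights` (4 cascade weights),
#'   `base_intensity`.
#' @export
control_params <- function() {
  list(dn = 0.06, lc = 3, weights = c(0.265, 0.255, 0.245, 0.235),
       base_intensity = 170)
}

#' @rdname control_params
#' @export
disease_params <- function() {
  list(dn = 0.12, lc = 6, weights = c(0.29, 0.26, 0.24, 0.21),
       base_intensity = 170)
}

# one synthetic tissue image: cascade modulation times correlated
# disorder, I = clip(base * C * (1 + g)) with C the mean-1 cascade field
synth_image <- function(side, params, seed) {
  set.seed(seed)
  casc <- multiplicative_cascade(params$weights, levels = log2(side))
  C <- casc$measure / mean(casc$measure)
  g <- gauss_field_exp(side, params$lc)
  g <- (g - mean(g)) / stats::sd(g) * params$dn
  gray_image(clip255(params$base_intensity * C * (1 + g)))
}

#' Generate labeled two-cohort synthetic image sets
#'
#' Emulates a control/disease imaging study: `n_per_group` images per
#' cohort, each the product of a randomized multiplicative cascade
#' (large-scale tissue texture with known multifractal spectrum) and a
#' correlated Gaussian disorder field (nanoscale refractive-index
#' fluctuations of strength `dn` and correlation length `lc`).
#' Deterministic given `seed`: per-image sub-seeds are drawn once from
#' the master seed and recorded in the manifest, so any image can be
#' regenerated in isolation.
#'
#' @param n_per_group images per cohort (default 10).
#' @param side image side, a power of two (default 512).
#' @param control,disease generating parameter lists, see
#'   [control_params()].
#' @param seed master seed.
#' @return A list: `images` (list of [gray_image()]s), `labels`
#'   (`"control"` / `"disease"`), `manifest` (data.frame of every
#'   generating parameter per image).
#' @export
make_cohorts <- function(n_per_group = 10L, side = 512L,
                         control = control_params(),
                         disease = disease_params(), seed = 1L) {
  stopifnot(n_per_group >= 1L)
  if (bitwAnd(as.integer(side), as.integer(side) - 1L) != 0L)
    stopf("side must be a power of two")
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 2L * n_per_group)
  labels <- rep(c("control", "disease"), each = n_per_group)
  pars <- list(control = control, disease = disease)
  images <- vector("list", 2L * n_per_group)
  manifest <- vector("list", 2L * n_per_group)
  for (i in seq_along(images)) {
    p <- pars[[labels[i]]]
    images[[i]] <- synth_image(side, p, sub[i])
    manifest[[i]] <- data.frame(image_id = sprintf("%s_%02d", labels[i],
                                                   ((i - 1L) %% n_per_group) + 1L),
                                group = labels[i], side = side,
                                dn = p$dn, lc = p$lc,
                                w1 = p$weights[1], w2 = p$weights[2],
                                w3 = p$weights[3], w4 = p$weights[4],
                                base_intensity = p$base_intensity,
                                seed = sub[i])
  }
  list(images = images, labels = labels, manifest = do.call(rbind, manifest))
}
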
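#' Transform parameters for the functional map
#'
#' `df_max` is the maximum fractal dimension recorded across the full
#' analyzed image set (both groups pooled); `epsilon_guard` is a small
#' positive offset keeping the transform finite for the sub-box that
#' attains `df_max`.
#'
#' @param df_max maximum recorded dimension, in `(0, 2]`.
#' @param epsilon_guard small positive guard (default `1e-6`).
#' @return A `transform_params` list.
#' @export
transform_params <- function(df_max, epsilon_guard = 1e-6) {
  if (!is.numeric(df_max) || df_max <= 0 || df_max > 2)
    stopf("df_max must lie in (0, 2]")
  if (epsilon_guard <= 0) stopf("epsilon_guard must be positive")
  structure(list(df_max = df_max, epsilon_guard = epsilon_guard),
            class = "transform_params")
}

map_values <- function(x) if (inherits(x, "fractal_map")) x$df else x

rewrap_map <- function(x, values) {
  if (!inherits(x, "fractal_map")) return(values)
  x$df <- values
  x$mean <- mean(values[is.finite(values)])
  x$std <- pop_sd(values)
  x
}

#' Elementwise natural logarithm of a fractal map
#'
#' `ln Df` sharpens relative contrasts for dimensions between 1 and e.
#' Non-positive entries (and missing ones) become `NA`.
#'
#' @param x a `fractal_map` or numeric vector/matrix of dimensions.
#' @return Same shape as the input, transformed.
#' @export
log_transform <- function(x) {
  v <- map_values(x)
  out <- ifelse(is.finite(v) & v > 0, log(pmax(v, .Machine$double.xmin)), NA_real_)
  dim(out) <- dim(v)
  rewrap_map(x, out)
}

#' Functional transform Dtf = Df / (Dfmax - Df)
#'
#' Strictly increasing in `Df`, the transform stretches spacing near the
#' recorded maximum dimension and broadens the right tail of the
#' distribution -- the regime where disease-related dense texture lives.
#' The guard keeps the sub-box attaining `df_max` finite:
#' `Dtf = Df / (df_max + epsilon_guard - Df)`.
#'
#' @param x a `fractal_map` or numeric vector/matrix.
#' @param params a [transform_params()]; alternatively give `df_max` (and
#'   optionally `epsilon_guard`) directly.
#' @param df_max,epsilon_guard used when `params` is missing.
#' @return Same shape as the input, transformed.
#' @export
functional_transform <- function(x, params = NULL, df_max = NULL,
                                 epsilon_guard = 1e-6) {
  if (is.null(params)) params <- transform_params(df_max, epsilon_guard)
  v <- map_values(x)
  fin <- v[is.finite(v)]
  if (length(fin) && max(fin) > params$df_max)
    stopf("df_max (%.6f) is below the largest map value (%.6f)",
          params$df_max, max(fin))
  out <- v / (params$df_max + params$epsilon_guard - v)
  dim(out) <- dim(v)
  rewrap_map(x, out)
}

#' Histogram summary of a metric distribution
#'
#' Equal-width bins spanning the data range, with bin counts normalized
#' to probabilities.  The 70-bin default matches the histogram resolution
#' used for the fractal-metric distributions.
#'
#' @param values numeric vector (at least 2 finite values).
#' @param n_bins number of bins (default 70).
#' @return A `distribution_summary`: `bin_edges`, `centers`, `prob`
#'   (summing to 1), `n`, and `degenerate` (TRUE when all values
#'   coincide, in which case a single bin holds all mass).
#' @export
estimate_distribution <- function(values, n_bins = 70L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stopf("need at least 2 finite values")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(structure(list(bin_edges = rng + c(-0.5, 0.5),
                          centers = rng[1], prob = 1,
                          n = length(values), degenerate = TRUE),
                     class = "distribution_summary"))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  structure(list(bin_edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 prob = counts / sum(counts),
                 n = length(values), degenerate = FALSE),
            class = "distribution_summary")
}

#' Polynomial smoothing of a histogram
#'
#' Least-squares polynomial fit (default degree 8) to the (bin center,
#' probability) pairs; fitted values are floored at zero.  Used to render
#' the distribution curves without random bin-to-bin fluctuation.
#'
#' @param summary a [estimate_distribution()] result.
#' @param degree polynomial degree, strictly below the number of bins.
#' @return The summary with a `smoothed` component (values at bin centers).
#' @export
polynomial_smooth <- function(summary, degree = 8L) {
  stopifnot(inherits(summary, "distribution_summary"))
  nb <- length(summary$centers)
  if (degree >= nb) stopf("degree (%d) must be below the number of bins (%d)",
                          degree, nb)
  fit <- stats::lm(y ~ stats::poly(x, degree),
                   data = data.frame(x = summary$centers, y = summary$prob))
  summary$smoothed <- unname(pmax(stats::fitted(fit), 0))
  summary$poly_degree <- degree
  summary
}

#' Gaussian approximation of a histogram
#'
#' Nonlinear least squares of `height * exp(-(x - peak)^2 / (2 sigma^2))`
#' to the bin probabilities, initialized at the histogram moments
#' (Levenberg-Marquardt, with a plain Gauss-Newton retry).  If the fit
#' fails to converge, the moment estimates are returned with
#' `converged = FALSE`.
#'
#' The `chi_square_score` is a goodness percentage,
#' `100 * (1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2))`, clamped to
#' `[0, 100]` -- an R-squared-style convention: 100 means the Gaussian
#' explains the histogram exactly.
#'
#' @param summary a [estimate_distribution()] result with >= 5 non-empty bins.
#' @return A `gaussian_fit` list: `peak` (location), `sigma`, `height`,
#'   `chi_square_score`, `converged`, `fitted` values at bin centers.
#' @export
gaussian_fit <- function(summary) {
  stopifnot(inherits(summary, "distribution_summary"))
  x <- summary$centers
  y <- summary$prob
  if (sum(y > 0) < 5L) stopf("need at least 5 non-empty bins for a Gaussian fit")
  mu0 <- sum(x * y)
  sd0 <- sqrt(max(sum((x - mu0)^2 * y), .Machine$double.eps))
  h0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ h * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(h = h0, mu = mu0, s = sd0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(stats::nls(y ~ h * exp(-(x - mu)^2 / (2 * s^2)),
                               start = list(h = h0, mu = mu0, s = sd0)),
                    error = function(e) NULL)
  if (is.null(fit)) {
    pars <- c(h = h0, mu = mu0, s = sd0); converged <- FALSE
  } else {
    pars <- stats::coef(fit); converged <- TRUE
  }
  fitted <- pars[["h"]] * exp(-(x - pars[["mu"]])^2 / (2 * pars[["s"]]^2))
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  score <- if (ss_tot == 0) ifelse(ss_res == 0, 100, 0)
           else 100 * (1 - ss_res / ss_tot)
  structure(list(peak = pars[["mu"]], sigma = abs(pars[["s"]]),
                 height = pars[["h"]],
                 chi_square_score = min(max(score, 0), 100),
                 converged = converged, fitted = fitted),
            class = "gaussian_fit")
}
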
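#' Percentage difference relative to a reference value
#'
#' `100 * difference / reference`; `NA` when the reference is zero.
#'
#' @param difference absolute difference.
#' @param reference reference (control-group) value.
#' @return Percentage.
#' @export
pct_difference <- function(difference, reference) {
  ifelse(reference == 0, NA_real_, 100 * difference / reference)
}

#' Control-versus-disease comparison of one metric
#'
#' Means and population standard deviations of the two pooled value
#' collections, their differences (disease minus control) and percentage
#' differences relative to the control value.  Feeding single summary
#' values reproduces printed-table arithmetic exactly (the mean of one
#' value is that value, its standard deviation 0).
#'
#' @param control,disease numeric collections (non-empty; `NA` dropped).
#' @param metric metric name for the output row.
#' @return A one-row `group_comparison` data.frame: `metric`,
#'   `control_mean`, `disease_mean`, `mean_difference`,
#'   `mean_pct_difference`, `control_std`, `disease_std`,
#'   `std_difference`, `std_pct_difference`.
#' @export
compare_groups <- function(control, disease, metric = "metric") {
  control <- control[is.finite(control)]
  disease <- disease[is.finite(disease)]
  if (length(control) == 0L || length(disease) == 0L)
    stopf("both groups must contain finite values")
  cm <- mean(control); dm <- mean(disease)
  cs <- pop_sd(control); ds <- pop_sd(disease)
  out <- data.frame(metric = metric,
                    control_mean = cm, disease_mean = dm,
                    mean_difference = dm - cm,
                    mean_pct_difference = pct_difference(dm - cm, cm),
                    control_std = cs, disease_std = ds,
                    std_difference = ds - cs,
                    std_pct_difference = pct_difference(ds - cs, cs))
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Analysis run configuration
#'
#' Bundles every tunable of the end-to-end pipeline.  Either pass
#' `images` + `labels`, or leave them `NULL` to simulate cohorts with
#' [make_cohorts()] under the given presets.
#'
#' @param images optional list of [gray_image()]s (standardized).
#' @param labels group label per image.
#' @param n_per_group,side,control,disease simulation settings when no
#'   images are given.
#' @param block_side sub-box side for the fractal map (default 32).
#' @param threshold_fraction binarization threshold (default 0.65).
#' @param n_bins histogram bins (default 70).
#' @param poly_degree polynomial smoothing degree (default 8).
#' @param epsilon_guard guard of the functional transform.
#' @param q_grid,mfa_scales multifractal settings (`NULL` mfa_scales picks
#'   dyadic scales from side/64 to side/4).
#' @param ipr_block_side,hopping IPR settings.
#' @param compute_mfa,compute_ipr stage switches.
#' @param seed master seed for simulation.
#' @return A `run_config` list.
#' @export
run_config <- function(images = NULL, labels = NULL,
                       n_per_group = 10L, side = 512L,
                       control = control_params(), disease = disease_params(),
                       block_side = 32L, threshold_fraction = 0.65,
                       n_bins = 70L, poly_degree = 8L, epsilon_guard = 1e-6,
                       q_grid = seq(-10, 10, by = 0.5), mfa_scales = NULL,
                       ipr_block_side = 32L, hopping = 1,
                       compute_mfa = TRUE, compute_ipr = TRUE, seed = 1L) {
  if (threshold_fraction < 0 || threshold_fraction > 1)
    stopf("threshold_fraction must lie in [0, 1]")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full multiparametric analysis
#'
#' Drives every stage on a labeled image set (real or simulated): per-image
#' fractal maps at the configured block side and threshold; pooled Df,
#' lnDf and lnDtf group comparisons (the comparison table has one row per
#' metric); histogram + polynomial + Gaussian distribution summaries of
#' lnDtf; per-image multifractal spectrum metrics with a width
#' comparison; and block IPR statistics.  Deterministic given the
#' configuration seed.
#'
#' @param cfg a [run_config()].
#' @return A `report_bundle` list: `comparison` (Df / lnDf / lnDtf rows),
#'   `df_values` (pooled per group), `df_max`, `distributions`,
#'   `mfa` (per-image metrics + width comparison), `ipr` (group stats),
#'   `manifest`, `config`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$images)) {
    sim <- make_cohorts(cfg$n_per_group, cfg$side, cfg$control, cfg$disease,
                        seed = cfg$seed)
    images <- sim$images; labels <- sim$labels; manifest <- sim$manifest
  } else {
    images <- cfg$images; labels <- cfg$labels; manifest <- NULL
    check_cohort(images, labels)
  }
  groups <- unique(labels)
  if (length(groups) != 2L) stopf("exactly two groups are required")

  maps <- lapply(images, function(im)
    fractal_map(binarize(im, cfg$threshold_fraction), block_side = cfg$block_side))
  df_pool <- lapply(groups, function(g)
    unlist(lapply(maps[labels == g], function(m) m$df[is.finite(m$df)])))
  names(df_pool) <- groups
  df_max <- max(unlist(df_pool))
  tp <- transform_params(df_max, cfg$epsilon_guard)

  vals <- list(
    Df = df_pool,
    lnDf = lapply(df_pool, function(v) log_transform(v)),
    lnDtf = lapply(df_pool, function(v) log_transform(functional_transform(v, tp))))
  comparison <- do.call(rbind, lapply(names(vals), function(m)
    compare_groups(vals[[m]][[1]], vals[[m]][[2]], metric = m)))

  distributions <- lapply(vals, function(v) lapply(v, function(x) {
    d <- estimate_distribution(x, n_bins = cfg$n_bins)
    if (!d$degenerate && cfg$poly_degree < length(d$centers))
      d <- polynomial_smooth(d, degree = cfg$poly_degree)
    d
  }))
  gauss <- tryCatch(
    lapply(distributions$lnDtf, gaussian_fit),
    error = function(e) NULL)

  mfa <- NULL
  if (cfg$compute_mfa) {
    side <- nrow(images[[1]]$pixels)
    scales <- cfg$mfa_scales
    if (is.null(scales)) scales <- 2^seq(max(2, log2(side) - 6), log2(side) - 2)
    met <- do.call(rbind, lapply(images, function(im)
      spectrum_metrics(mf_spectrum(im, q_grid = cfg$q_grid, scales = scales))))
    met$group <- labels
    mfa <- list(metrics = met,
                width_comparison = compare_groups(
                  met$width[labels == groups[1]],
                  met$width[labels == groups[2]], metric = "mfa_width"))
  }

  ipr <- NULL
  if (cfg$compute_ipr) {
    im_res <- lapply(images, ipr_map, block_side = cfg$ipr_block_side,
                     hopping = cfg$hopping)
    ipr <- list(per_image = im_res,
                stats = group_ipr_stats(im_res, labels,
                                        control_label = groups[1]))
  }

  structure(list(comparison = comparison, df_values = vals, df_max = df_max,
                 distributions = distributions, gaussian_fits = gauss,
                 mfa = mfa, ipr = ipr, manifest = manifest, config = cfg),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Group comparison (pooled sub-box values):\n")
  print(format(x$comparison, digits = 4), row.names = FALSE)
  if (!is.null(x$mfa))
    cat(sprintf("\nMultifractal width: control %.4f, disease %.4f\n",
                x$mfa$width_comparison$control_mean,
                x$mfa$width_comparison$disease_mean))
  if (!is.null(x$ipr)) {
    cat("\nIPR group statistics:\n")
    print(format(x$ipr$stats, digits = 4), row.names = FALSE)
  }
  invisible(x)
}
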
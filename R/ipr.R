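#' Optical potential of an image block
#'
#' On-site energies of the effective optical lattice: the relative
#' intensity fluctuation `eps_i = (I - I0) / I0` with `I0` the block mean
#' intensity.  Since intensity is proportional to local mass density (and
#' refractive index), `eps_i` stands in for the relative refractive-index
#' fluctuation `dn / n0`.  Zero-mean by construction and invariant under
#' a global rescaling of the intensities.
#'
#' @param block a square [gray_image()] block with positive mean intensity.
#' @return An `optical_potential`: `values` (L x L matrix), `i0`,
#'   `block_coord`.
#' @export
optical_potential <- function(block) {
  stopifnot(inherits(block, "gray_image"))
  p <- block$pixels
  if (nrow(p) != ncol(p)) stopf("block must be square")
  i0 <- mean(p)
  if (i0 <= 0) stopf("degenerate block: zero mean intensity")
  structure(list(values = (p - i0) / i0, i0 = i0,
                 block_coord = c(block$block_row, block$block_col)),
            class = "optical_potential")
}

#' Tight-binding Hamiltonian on an L x L lattice
#'
#' Dense symmetric operator `H = sum_i eps_i |i><i| + t sum_<ij> (|i><j| +
#' |j><i|)` with nearest-neighbor hopping on the open (hard-wall) square
#' lattice; sites are indexed row-major.  An open L x L grid has
#' `2 L (L - 1)` neighbor pairs.
#'
#' @param pot an [optical_potential()] (or plain L x L matrix of on-site
#'   energies), L >= 2.
#' @param t hopping amplitude (overlap integral); `t = 1` sets the energy
#'   unit.
#' @return A `tb_hamiltonian`: `matrix` (L^2 x L^2), `L`, `t`, `n_pairs`.
#' @export
build_hamiltonian <- function(pot, t = 1) {
  v <- if (inherits(pot, "optical_potential")) pot$values else as.matrix(pot)
  L <- nrow(v)
  if (L < 2L || ncol(v) != L) stopf("need a square lattice with L >= 2")
  N <- L * L
  H <- matrix(0, N, N)
  diag(H) <- as.vector(t(v))            # row-major site order
  idx <- function(r, c) (r - 1L) * L + c
  for (r in seq_len(L)) for (c in seq_len(L)) {
    i <- idx(r, c)
    if (r < L) { j <- idx(r + 1L, c); H[i, j] <- t; H[j, i] <- t }
    if (c < L) { j <- i + 1L;         H[i, j] <- t; H[j, i] <- t }
  }
  structure(list(matrix = H, L = L, t = t, n_pairs = 2L * L * (L - 1L)),
            class = "tb_hamiltonian")
}

#' Inverse participation ratio of a normalized state
#'
#' For a unit-normalized eigenvector psi, the raw IPR is `sum |psi|^4`
#' (1/N for a fully extended state, 1 for a single-site state).  The
#' area-normalized report multiplies by the number of sites N so the
#' extended-state floor is O(1) and localization raises the value.
#'
#' @param v state amplitudes (normalized internally).
#' @param area_normalized multiply by N (default TRUE).
#' @return The IPR.
#' @export
state_ipr <- function(v, area_normalized = TRUE) {
  v2 <- v^2
  raw <- sum(v2^2) / sum(v2)^2
  if (area_normalized) length(v) * raw else raw
}

#' Full eigen-decomposition IPR of a tight-binding block
#'
#' Diagonalizes the Hamiltonian and computes the IPR of every
#' eigenfunction; all `N = L^2` states enter the block mean (no energy
#' windowing).  Both the raw `sum psi^4` and the area-normalized `N *
#' sum psi^4` conventions are returned.
#'
#' @param H a [build_hamiltonian()] result.
#' @return An `eigen_ipr` list: `ipr_raw`, `ipr` (area-normalized,
#'   per state), `block_mean`, `block_mean_raw`, `eigenvalues`.
#' @export
eigen_ipr <- function(H) {
  stopifnot(inherits(H, "tb_hamiltonian"))
  e <- eigen(H$matrix, symmetric = TRUE)
  raw <- colSums(e$vectors^4)
  N <- H$L^2
  structure(list(ipr_raw = raw, ipr = N * raw,
                 block_mean = N * mean(raw), block_mean_raw = mean(raw),
                 eigenvalues = e$values),
            class = "eigen_ipr")
}

#' Block IPR heatmap of an image
#'
#' Partitions the image into `block_side` blocks, builds the optical
#' potential and tight-binding Hamiltonian of each, and maps the block
#' mean area-normalized IPR -- the localization heatmap.  Blocks with zero
#' mean intensity are skipped (`NA`).
#'
#' @param img a square [gray_image()] (typically the red channel).
#' @param block_side lattice side per block (default 32, i.e. 16 x 16 =
#'   256 heatmap cells on a 512 image).
#' @param hopping hopping amplitude `t`.
#' @return An `ipr_result`: `per_block` (grid of block means), `per_block_raw`,
#'   `image_mean`, `image_std` (population convention over defined blocks),
#'   `block_side`, `hopping`.
#' @export
ipr_map <- function(img, block_side = 32L, hopping = 1) {
  stopifnot(inherits(img, "gray_image"))
  blocks <- partition(img, block_side)
  g <- as.integer(sqrt(length(blocks)))
  per <- matrix(NA_real_, g, g)
  for (b in blocks) {
    if (mean(b$pixels) <= 0) next
    ei <- eigen_ipr(build_hamiltonian(optical_potential(b), t = hopping))
    per[b$block_row, b$block_col] <- ei$block_mean
  }
  structure(list(per_block = per,
                 per_block_raw = per / block_side^2,
                 image_mean = mean(per[is.finite(per)]),
                 image_std = pop_sd(per),
                 block_side = block_side, hopping = hopping),
            class = "ipr_result")
}

#' @export
print.ipr_result <- function(x, ...) {
  cat(sprintf("<ipr_result %d x %d blocks (L = %d): mean %.4f, STD %.4f>\n",
              nrow(x$per_block), ncol(x$per_block), x$block_side,
              x$image_mean, x$image_std))
  invisible(x)
}

#' Lattice-size sweep of the IPR
#'
#' Pooled per-group block IPR statistics across a ladder of block sides
#' (2, 4, 8, 16, 32 by default), tracing how the control/disease gap
#' grows with the analysis scale.
#'
#' @param images list of square [gray_image()]s.
#' @param labels group label per image.
#' @param block_sides lattice sides to sweep.
#' @param hopping hopping amplitude.
#' @return A `sweep_table` data.frame: `parameter`, `value`, `group`,
#'   `mean`, `std`, `n`.
#' @export
sweep_ipr_scale <- function(images, labels, block_sides = c(2L, 4L, 8L, 16L, 32L),
                            hopping = 1) {
  check_cohort(images, labels)
  out <- do.call(rbind, lapply(block_sides, function(b) {
    vals <- lapply(images, function(im) ipr_map(im, block_side = b,
                                                hopping = hopping)$per_block)
    pool_df_stats(vals, labels, "ipr_block_side", b)
  }))
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Group-level IPR statistics
#'
#' Pools all defined block-level IPR values of each group and reports the
#' group mean and population standard deviation plus differences relative
#' to the control group.
#'
#' @param results list of [ipr_map()] results.
#' @param labels group label per result.
#' @param control_label which label is the reference group (default the
#'   first in `labels`).
#' @return A data.frame with one row per group (`group`, `mean`, `std`,
#'   `n_blocks`) carrying attributes `mean_pct_difference` and
#'   `std_pct_difference` for the two-group case.
#' @export
group_ipr_stats <- function(results, labels, control_label = labels[[1]]) {
  check_cohort(results, labels)
  groups <- unique(c(control_label, labels))
  tab <- do.call(rbind, lapply(groups, function(g) {
    v <- unlist(lapply(results[labels == g], function(r) r$per_block))
    v <- v[is.finite(v)]
    data.frame(group = g, mean = mean(v), std = pop_sd(v), n_blocks = length(v))
  }))
  if (nrow(tab) == 2L) {
    attr(tab, "mean_pct_difference") <- 100 * (tab$mean[2] - tab$mean[1]) / tab$mean[1]
    attr(tab, "std_pct_difference") <- 100 * (tab$std[2] - tab$std[1]) / tab$std[1]
  }
  tab
}
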
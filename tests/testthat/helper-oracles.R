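# independent oracles used across test files -- kept deliberately naive

# double-loop box count: for each grid cell, scan its pixels directly
brute_box_count <- function(m, eps) {
  side <- nrow(m)
  n <- 0L
  for (r in seq(1, side, by = eps)) {
    for (c in seq(1, side, by = eps)) {
      hit <- FALSE
      for (i in r:(r + eps - 1)) for (j in c:(c + eps - 1))
        if (m[i, j]) { hit <- TRUE; break }
      if (hit) n <- n + 1L
    }
  }
  n
}

# double-loop box-mass sums for the multifractal measure
brute_box_sums <- function(p, eps) {
  side <- nrow(p)
  g <- side / eps
  out <- matrix(0, g, g)
  for (r in 1:g) for (c in 1:g) {
    s <- 0
    for (i in ((r - 1) * eps + 1):(r * eps))
      for (j in ((c - 1) * eps + 1):(c * eps)) s <- s + p[i, j]
    out[r, c] <- s
  }
  out
}

# clean open-boundary L x L lattice mean area-normalized IPR, frozen from a
# one-off direct diagonalization (LAPACK basis within degenerate subspaces)
CLEAN_LATTICE_IPR_32 <- 2.450191013425391

rand_binary_block <- function(side = 32, p = 0.3) {
  binary_image(matrix(runif(side * side) < p, side, side))
}
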
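test_that("optical potential is the zero-mean relative intensity fluctuation", {
  u <- optical_potential(gray_image(matrix(120, 8, 8)))
  expect_equal(u$values, matrix(0, 8, 8))
  expect_equal(u$i0, 120)

  # 2x2 block by hand: pixels (100, 50, 50, 50), I0 = 62.5
  m <- matrix(c(100, 50, 50, 50), 2)
  p <- optical_potential(gray_image(m))
  expect_equal(p$values, (m - 62.5) / 62.5)
  expect_equal(mean(p$values), 0, tolerance = 1e-12)

  # doubling intensities leaves the potential unchanged
  p2 <- optical_potential(gray_image(2 * m))
  expect_equal(p2$values, p$values)
  expect_error(optical_potential(gray_image(matrix(0, 4, 4))), "zero mean")
})

test_that("the tight-binding Hamiltonian has the right structure and spectrum", {
  H2 <- build_hamiltonian(matrix(0, 2, 2), t = 1)
  expect_equal(sort(eigen(H2$matrix, symmetric = TRUE)$values),
               c(-2, 0, 0, 2), tolerance = 1e-12)
  expect_equal(H2$n_pairs, 4)

  H3 <- build_hamiltonian(matrix(0, 3, 3))
  expect_equal(H3$n_pairs, 12)                     # 2 * 3 * 2
  expect_equal(sum(H3$matrix != 0) / 2, 12)        # off-diagonal entries
  expect_identical(H3$matrix, t(H3$matrix))        # exact symmetry

  # constant shift of the on-site energies shifts eigenvalues exactly
  set.seed(15)
  eps <- matrix(rnorm(16, sd = 0.3), 4)
  e0 <- eigen(build_hamiltonian(eps)$matrix, symmetric = TRUE)$values
  e1 <- eigen(build_hamiltonian(eps + 0.7)$matrix, symmetric = TRUE)$values
  expect_equal(e1, e0 + 0.7, tolerance = 1e-12)
})

test_that("state IPR hits the extended floor and localized ceiling", {
  N <- 1024
  expect_equal(state_ipr(rep(1 / sqrt(N), N)), 1.0, tolerance = 1e-12)
  delta <- c(1, rep(0, N - 1))
  expect_equal(state_ipr(delta), N)
  expect_equal(state_ipr(delta, area_normalized = FALSE), 1)
})

test_that("eigen_ipr reproduces the frozen clean-lattice constant", {
  ei <- eigen_ipr(build_hamiltonian(matrix(0, 32, 32)))
  expect_equal(ei$block_mean, CLEAN_LATTICE_IPR_32, tolerance = 1e-8)
  expect_equal(ei$ipr, 1024 * ei$ipr_raw)
  # every reported state IPR within the rigorous bounds [1, N]
  expect_true(all(ei$ipr >= 1 - 1e-9 & ei$ipr <= 1024 + 1e-9))
})

test_that("eigenvectors are orthonormal and disorder raises the block IPR", {
  set.seed(23)
  eps <- matrix(rnorm(1024, sd = 0.5), 32)
  H <- build_hamiltonian(eps)
  e <- eigen(H$matrix, symmetric = TRUE)
  G <- crossprod(e$vectors)
  expect_lt(max(abs(G - diag(1024))), 1e-8)
  ei <- eigen_ipr(H)
  expect_true(all(ei$ipr >= 1 - 1e-9))
  expect_gt(ei$block_mean, CLEAN_LATTICE_IPR_32)   # strong disorder localizes
})

test_that("ipr_map produces one heatmap cell per block and flags fixtures", {
  u <- gray_image(matrix(150, 64, 64))
  r <- ipr_map(u, 32)
  expect_equal(dim(r$per_block), c(2, 2))
  expect_equal(as.vector(r$per_block), rep(CLEAN_LATTICE_IPR_32, 4),
               tolerance = 1e-8)
  expect_equal(r$image_std, 0, tolerance = 1e-9)

  # one strongly disordered block in an otherwise uniform image
  m <- matrix(150, 64, 64)
  set.seed(9)
  m[33:64, 33:64] <- 150 * (1 + 0.4 * rnorm(1024))
  m <- pmin(pmax(m, 0), 255)
  r2 <- ipr_map(gray_image(m), 32)
  expect_gt(r2$per_block[2, 2], max(r2$per_block[1, 1], r2$per_block[1, 2],
                                    r2$per_block[2, 1]) + 0.2)
})

test_that("group statistics pool blocks exactly as a flat recomputation", {
  set.seed(33)
  imgs <- lapply(1:4, function(i)
    disorder_field(64, dn = c(0.05, 0.05, 0.2, 0.2)[i], lc = 3, 160, seed = i))
  labs <- c("control", "control", "disease", "disease")
  res <- lapply(imgs, ipr_map, block_side = 32)
  st <- group_ipr_stats(res, labs)
  for (g in c("control", "disease")) {
    v <- unlist(lapply(res[labs == g], function(r) r$per_block))
    expect_equal(st$mean[st$group == g], mean(v))
    expect_equal(st$std[st$group == g], sqrt(mean((v - mean(v))^2)))
  }
  expect_equal(attr(st, "mean_pct_difference"),
               100 * diff(st$mean) / st$mean[1])
  st_id <- group_ipr_stats(res[c(1, 1)], c("a", "b"))
  expect_equal(attr(st_id, "mean_pct_difference"), 0)

  # higher disorder group localizes more
  expect_gt(st$mean[st$group == "disease"], st$mean[st$group == "control"])
})

test_that("the IPR scale sweep reports a per-side group table", {
  set.seed(44)
  imgs <- list(disorder_field(32, 0.05, 2, 160, seed = 1),
               disorder_field(32, 0.3, 2, 160, seed = 2))
  sw <- sweep_ipr_scale(imgs, c("low", "high"), block_sides = c(8, 16, 32))
  expect_equal(nrow(sw), 6)
  expect_true(all(sw$std >= 0))
  # uniform cohorts: zero gap at every side
  uim <- list(gray_image(matrix(100, 32, 32)), gray_image(matrix(100, 32, 32)))
  swu <- sweep_ipr_scale(uim, c("a", "b"), block_sides = c(8, 16))
  for (v in unique(swu$value))
    expect_equal(diff(swu$mean[swu$value == v]), 0)
})
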
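test_that("box counts match closed forms on full and single-pixel blocks", {
  full <- binary_image(matrix(TRUE, 32, 32))
  cv <- box_count(full, c(2, 4, 8, 16))
  expect_equal(cv$counts, c(256L, 64L, 16L, 4L))
  expect_equal(fit_dimension(cv), 2.0)

  one <- matrix(FALSE, 32, 32); one[7, 19] <- TRUE
  cv1 <- box_count(binary_image(one), c(2, 4, 8, 16))
  expect_equal(cv1$counts, rep(1L, 4))
  expect_equal(fit_dimension(cv1), 0.0)

  expect_error(box_count(full, c(3, 4)), "divide")
})

test_that("box_count equals a brute-force double loop on random blocks", {
  set.seed(42)
  for (i in 1:100) {
    blk <- rand_binary_block(32, p = runif(1, 0.02, 0.9))
    cv <- box_count(blk, c(2, 4, 8, 16))
    expect_identical(cv$counts,
                     vapply(c(2, 4, 8, 16),
                            function(e) brute_box_count(blk$pixels, e),
                            integer(1)))
  }
})

test_that("counts are non-increasing in scale and dimensions stay in [0, 2]", {
  set.seed(7)
  for (i in 1:25) {
    blk <- rand_binary_block(32, p = runif(1, 0, 1))
    cv <- box_count(blk, c(2, 4, 8, 16))
    expect_true(all(diff(cv$counts) <= 0))
    d <- fit_dimension(cv)
    if (is.finite(d)) expect_true(d >= 0 && d <= 2)
  }
})

test_that("deterministic fractals are recovered near their analytic dimension", {
  sc <- sierpinski_carpet(5)                       # 243 x 243
  d_sc <- fit_dimension(box_count(sc, 3^(1:4)))
  expect_lt(abs(d_sc - log(8) / log(3)), 0.05)

  vc <- vicsek_cross(5)
  d_vc <- fit_dimension(box_count(vc, 3^(1:4)))
  expect_lt(abs(d_vc - log(5) / log(3)), 0.05)
})

test_that("degenerate blocks yield a missing dimension, not zero", {
  empty <- binary_image(matrix(FALSE, 32, 32))
  expect_true(is.na(fit_dimension(box_count(empty, c(2, 4, 8, 16)))))
})

test_that("fractal_map has one entry per sub-box and flags empty blocks", {
  full <- binary_image(matrix(TRUE, 512, 512))
  fm <- fractal_map(full, 32)
  expect_equal(dim(fm$df), c(16, 16))
  expect_true(all(fm$df == 2))
  expect_equal(fm$std, 0)

  m <- matrix(TRUE, 64, 64)
  m[33:64, 1:32] <- FALSE                          # block (2, 1) empty
  fm2 <- fractal_map(binary_image(m), 32)
  expect_true(is.na(fm2$df[2, 1]))
  expect_equal(sum(is.na(fm2$df)), 1)
  expect_equal(fm2$mean, mean(fm2$df[-2]))
})

test_that("length-scale sweep pools per group with sane spread behaviour", {
  allfg <- gray_image(matrix(0, 128, 128))         # all below any positive cut
  sw <- sweep_length_scale(list(allfg), labels = "g",
                           block_sides = c(32, 64, 128),
                           threshold_fraction = 0.65)
  expect_equal(sw$mean, rep(2, 3))
  expect_equal(sw$std, rep(0, 3))

  set.seed(9)
  imgs <- lapply(1:3, function(i) disorder_field(128, 0.25, 3, 150, seed = i))
  sw2 <- sweep_length_scale(imgs, rep("a", 3), block_sides = c(32, 128),
                            threshold_fraction = 0.65)
  # one value per image at the full side vs 16 per image at 32
  expect_equal(sw2$n, c(3 * 16, 3))
  expect_lte(sw2$std[sw2$value == 128], sw2$std[sw2$value == 32])

  # identical groups give identical rows
  sw3 <- sweep_length_scale(c(imgs, imgs), rep(c("a", "b"), each = 3),
                            block_sides = c(32, 64), threshold_fraction = 0.65)
  expect_equal(sw3$mean[sw3$group == "a"], sw3$mean[sw3$group == "b"])
  expect_equal(sw3$std[sw3$group == "a"], sw3$std[sw3$group == "b"])
})

test_that("threshold sweep saturates correctly and locates the best gaps", {
  set.seed(21)
  # intensities bounded well below 255 so the saturation limit is exact
  light <- lapply(1:2, function(i) disorder_field(64, 0.08, 2, 170, seed = i))
  dark  <- lapply(1:2, function(i) disorder_field(64, 0.12, 2, 140, seed = 10 + i))
  imgs <- c(light, dark); labs <- rep(c("a", "b"), each = 2)
  fr <- c(0.45, 0.65, 0.8, 0.95)
  sw <- sweep_threshold(imgs, labs, fractions = fr, block_side = 32)

  # fraction 1.0: every pixel below 255 -> all foreground -> mean 2
  swa <- sweep_threshold(imgs, labs, fractions = 1.0, block_side = 32)
  expect_equal(swa$mean, c(2, 2))
  # fraction 0: no foreground -> all degenerate, missing means
  sw0 <- sweep_threshold(imgs, labs, fractions = 0, block_side = 32)
  expect_true(all(is.na(sw0$mean)))

  # argmax attributes agree with a direct scan of the table
  gap <- function(col) vapply(fr, function(f) {
    abs(diff(sw[sw$value == f, col])) }, numeric(1))
  expect_equal(attr(sw, "best_mean_gap_fraction"), fr[which.max(gap("mean"))])
  expect_equal(attr(sw, "best_std_gap_fraction"), fr[which.max(gap("std"))])
})
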
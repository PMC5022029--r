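test_that("calibration recovers factors forced by construction", {
  # donor-only: B = 0.1 * A, C = 0
  A <- matrix(c(rep(0, 50), seq(100, 1000, length.out = 50)), 10, 10)
  donor <- fret_images(A, 0.1 * A, matrix(0, 10, 10))
  # acceptor-only: B = 0.05 * C, A = 0.01 * C
  C <- matrix(c(rep(0, 50), seq(200, 2000, length.out = 50)), 10, 10)
  acceptor <- fret_images(0.01 * C, 0.05 * C, C)
  f <- fret_calibrate(donor, acceptor)
  expect_equal(f$beta, 0.1)
  expect_equal(f$delta, 0)
  expect_equal(f$gamma, 0.05)
  expect_equal(f$alpha, 0.01)

  blank <- fret_images(matrix(0, 10, 10), matrix(0, 10, 10), matrix(0, 10, 10))
  expect_error(fret_calibrate(blank, acceptor), "calibration")
})

test_that("calibration recovers factors from noisy synthetic controls", {
  g <- gen_fret_images(E_true = 0.2, noise_mult = 0.05, seed = 11)
  f <- fret_calibrate(g$donor_only, g$acceptor_only)
  truth <- g$truth$factors
  expect_equal(f$alpha, truth$alpha, tolerance = 0.02)
  expect_equal(f$beta, truth$beta, tolerance = 0.02)
  expect_equal(f$gamma, truth$gamma, tolerance = 0.02)
  expect_lt(abs(f$delta - truth$delta), 0.002)
})

test_that("efficiency map behaves as the estimator dictates", {
  f <- fret_factors(alpha = 0.02, beta = 0.12, gamma = 0.08, delta = 0.01)
  A <- matrix(500, 8, 8); C <- matrix(700, 8, 8)
  Ac <- A - f$alpha * C
  Cc <- C - f$delta * A

  # B carrying only bleed-through: E = 0 everywhere
  B0 <- f$beta * Ac + f$gamma * Cc
  E0 <- efret_image(fret_images(A, B0, C), f)
  expect_true(all(E0 == 0))

  # corrected FRET equal to corrected donor: E = 0.5
  B5 <- Ac + f$beta * Ac + f$gamma * Cc
  E5 <- efret_image(fret_images(A, B5, C), f)
  expect_true(all(abs(E5 - 0.5) < 1e-12))

  # degenerate pixels (A' <= 0) are masked
  Em <- efret_image(fret_images(matrix(0, 2, 2), matrix(5, 2, 2),
                                matrix(10, 2, 2)), f)
  expect_true(all(is.na(Em)))
})

test_that("E is invariant under uniform intensity rescaling", {
  g <- gen_fret_images(E_true = 0.4, noise_mult = 0, noise_add = 0,
                       background = c(0, 0, 0), seed = 12)
  f <- do.call(fret_factors, g$truth$factors)
  E1 <- efret_image(g$sample, f)
  scaled <- fret_images(3.7 * g$sample$A, 3.7 * g$sample$B, 3.7 * g$sample$C)
  E2 <- efret_image(scaled, f)
  expect_equal(E1, E2, tolerance = 1e-12)
})

test_that("vectorized map equals pixel-by-pixel scalar evaluation", {
  g <- gen_fret_images(E_true = 0.3, dim = 32, n_clusters = 5, seed = 13)
  f <- do.call(fret_factors, g$truth$factors)
  E <- efret_image(g$sample, f)
  scalar_E <- function(a, b, c) {
    a0 <- max(a - g$sample$background[1], 0)
    b0 <- max(b - g$sample$background[2], 0)
    c0 <- max(c - g$sample$background[3], 0)
    ac <- a0 - f$alpha * c0
    cc <- c0 - f$delta * a0
    fc <- b0 - f$beta * ac - f$gamma * cc
    if (ac <= 0) return(NA_real_)
    min(max(fc / (fc + ac), 0), 1)
  }
  idx <- cbind(sample(32, 60, TRUE), sample(32, 60, TRUE))
  manual <- mapply(function(i, j)
    scalar_E(g$sample$A[i, j], g$sample$B[i, j], g$sample$C[i, j]),
    idx[, 1], idx[, 2])
  expect_equal(E[idx], manual)
})

test_that("zero-noise round trip inverts the forward model exactly", {
  for (E_true in c(0, 0.15, 0.89)) {
    g <- gen_fret_images(E_true = E_true, noise_mult = 0, noise_add = 0,
                         n_clusters = 20, dim = 96, seed = 14)
    f <- do.call(fret_factors, g$truth$factors)
    res <- cluster_fret(g$sample, f, g$masks)
    expect_equal(res$E_fret, rep(E_true, nrow(res)), tolerance = 1e-9)
  }
})

test_that("acceptor/donor ratio filter excludes expression outliers", {
  f <- fret_factors()
  dimi <- 30
  lab <- matrix(0L, dimi, dimi)
  lab[2:4, 2:4] <- 1L; lab[12:14, 12:14] <- 2L; lab[22:24, 22:24] <- 3L
  A <- matrix(0, dimi, dimi); C <- matrix(0, dimi, dimi)
  A[lab > 0] <- 100
  C[lab == 1] <- 100; C[lab == 2] <- 100; C[lab == 3] <- 10000  # ratio 100
  B <- 0.3 * A
  res <- cluster_fret(fret_images(A, B, C), f, lab)
  expect_identical(res$included, c(TRUE, TRUE, FALSE))

  # a single cluster is always included: its ratio equals the day mean
  res1 <- cluster_fret(fret_images(A, B, C), f, list(lab == 1))
  expect_true(res1$included)
})

test_that("cluster segmentation helper finds the true clusters", {
  skip_if_not_installed("EBImage")
  g <- gen_fret_images(E_true = 0.2, n_clusters = 12, dim = 96, seed = 15)
  lab <- segment_clusters(g$sample$C - g$sample$background[3], q = 0.9)
  expect_gte(max(lab), 10)
  # most labelled pixels coincide with true cluster pixels
  overlap <- mean(g$masks[lab > 0] > 0)
  expect_gt(overlap, 0.9)
})
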
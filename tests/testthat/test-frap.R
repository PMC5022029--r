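test_that("normalization reduces to the textbook form without autobleaching", {
  t <- seq(-5, 60, by = 1)
  post <- t >= 0
  F0 <- 0.3
  rec <- ifelse(post, F0 + (1 - F0) * 0.9 * (1 - exp(-pmax(t, 0) / 20)), 1)
  tr <- frap_trace(t, rec, rep(1, length(t)))
  cv <- frap_normalize(tr)
  expect_equal(cv$R, (rec[post] - F0) / (1 - F0), tolerance = 1e-12)
  expect_equal(cv$t, t[post])
  expect_equal(cv$R[1], 0)
})

test_that("shared autobleaching cancels exactly in the region ratio", {
  t <- seq(-5, 120, by = 1)
  post <- t >= 0
  F0 <- 0.25
  clean <- ifelse(post, F0 + (1 - F0) * 0.8 * (1 - exp(-pmax(t, 0) / 50)), 1)
  ab <- exp(-0.002 * (t + 5))       # both regions halved the same way
  tr_ab <- frap_trace(t, clean * ab, ab)
  tr_clean <- frap_trace(t, clean, rep(1, length(t)))
  expect_equal(frap_normalize(tr_ab)$R, frap_normalize(tr_clean)$R,
               tolerance = 1e-10)
})

test_that("normalization flags degenerate traces", {
  t <- seq(-5, 30)
  expect_error(frap_trace(t[1:5], rep(1, 5), rep(1, 5), bleach_frame = 2),
               "pre-bleach")
  tr <- frap_trace(t, c(rep(1, 5), rep(0.2, 31)), rep(1, 36))
  tr$F_control <- c(rep(1, 5), 0, rep(1, 30))
  expect_error(frap_normalize(tr), "positive")
  # noisy pre-bleach baseline warns
  set.seed(1)
  noisy_pre <- c(1, 2, 0.4, 1.5, 1, rep(0.2, 31))
  tr2 <- frap_trace(t, noisy_pre, rep(1, 36), bleach_frame = 6)
  expect_warning(frap_normalize(tr2), "pre-bleach")
})

test_that("bleach frame is detected at the largest single-frame drop", {
  g <- gen_frap_trace(seed = 3)
  tr2 <- frap_trace(g$t, g$F_bleach, g$F_control)   # re-detect
  expect_identical(tr2$bleach_frame, g$bleach_frame)
})

test_that("noiseless recovery is fitted exactly", {
  tr <- gen_frap_trace(tau = 100, M = 1, noise_sd = 0, autobleach = 0)
  fit <- frap_fit(frap_normalize(tr))
  expect_equal(fit$tau, 100, tolerance = 1e-6)
  expect_equal(fit$M, 1, tolerance = 1e-6)

  tr2 <- gen_frap_trace(tau = 427, M = 0.8, noise_sd = 0, autobleach = 0.1)
  fit2 <- frap_fit(frap_normalize(tr2))
  expect_equal(fit2$tau, 427, tolerance = 0.02)
  expect_equal(fit2$M, 0.8, tolerance = 0.02)
})

test_that("continuous fit beats a brute-force grid search", {
  set.seed(7)
  cv <- frap_normalize(gen_frap_trace(tau = 427, seed = 7))
  fit <- frap_fit(cv)
  sse <- sum(residuals(fit)^2)
  # independent oracle: exhaustive search over (tau, M)
  taus <- seq(1, 2000, by = 1)
  Ms <- seq(0.1, 1.05, by = 0.01)
  sse_grid <- min(vapply(Ms, function(M) {
    pred <- outer(cv$t, taus, function(tt, ta) 1 - exp(-tt / ta))
    min(colSums((M * pred - cv$R)^2))
  }, numeric(1)))
  expect_lte(sse, sse_grid * 1.01)
})

test_that("tau scales linearly with a uniform time rescaling", {
  cv <- frap_normalize(gen_frap_trace(tau = 200, seed = 9))
  fit1 <- frap_fit(cv)
  cv_min <- cv
  cv_min$t <- cv$t / 60   # express time in minutes
  fit2 <- frap_fit(cv_min)
  expect_equal(fit2$tau * 60, fit1$tau, tolerance = 1e-4)
  expect_equal(fit2$M, fit1$M, tolerance = 1e-6)
})

test_that("the fitted model is non-decreasing and tau recovery is unbiased", {
  grid <- expand.grid(tau = c(100, 427, 710, 1000), M = c(0.5, 0.8, 1.0))
  bias <- mapply(function(tau, M) {
    est <- vapply(1:12, function(s) {
      cv <- frap_normalize(gen_frap_trace(tau = tau, M = M, noise_sd = 0.02,
                                          seed = 997 * s + tau +
                                            round(100 * M)))
      fit <- frap_fit(cv)
      expect_true(all(diff(predict(fit)) >= 0))
      fit$tau
    }, numeric(1))
    (median(est) - tau) / tau
  }, grid$tau, grid$M)
  # across the whole grid the median bias is small ...
  expect_lt(abs(median(bias)), 0.05)
  # ... and cells whose recording spans most of a time constant with a
  # high mobile fraction are individually well identified; the remaining
  # corner (tau >> recording length at low M) is the documented tau-M
  # anti-correlation regime and is not individually constrained.
  well <- grid$tau <= 427 & grid$M >= 0.8
  expect_true(all(abs(bias[well]) < 0.1))
})

test_that("FRAP traces round-trip through CSV", {
  g <- gen_frap_trace(seed = 21)
  path <- tempfile(fileext = ".csv")
  write_frap_csv(g, path)
  back <- read_frap_csv(path)
  expect_equal(back$F_bleach, g$F_bleach, tolerance = 1e-10)
  expect_identical(back$bleach_frame, g$bleach_frame)
  unlink(path)
})
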
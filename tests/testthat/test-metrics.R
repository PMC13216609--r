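test_that("psnr matches the closed form and flags identical images", {
  a <- matrix(0.2, 16, 16)
  expect_equal(psnr(a, a + 0.1), 20, tolerance = 1e-12)
  expect_identical(psnr(a, a), Inf)
  expect_error(psnr(a, matrix(0.2, 8, 8)), "dimensions")
  # peak convention: 1.0 on the normalized scale
  expect_equal(psnr(a, a + 0.1, peak = 1), 10 * log10(1 / 0.01))
})

test_that("psnr and ssim agree with independent brute-force oracles", {
  for (i in 1:100) {
    a <- rand_img(16, 16, seed = i)
    b <- rand_img(16, 16, seed = 1000 + i)
    mse <- sum((a - b)^2) / length(a)
    expect_lt(abs(psnr(a, b) - 10 * log10(1 / mse)), 1e-10)
    expect_lt(abs(ssim(a, b) - ssim_oracle(a, b)), 1e-8)
  }
})

test_that("ssim is 1 for identical images, symmetric, and sign-sensitive", {
  a <- rand_img(32, 32, seed = 7)
  expect_identical(ssim(a, a), 1)
  b <- rand_img(32, 32, seed = 8)
  expect_lt(abs(ssim(a, b) - ssim(b, a)), 1e-12)
  # structure inversion on a two-level image flips the sign
  binary <- matrix(rep(c(0, 1), length.out = 32 * 32), 32, 32)
  expect_lt(ssim(binary, 1 - binary), 0)
  expect_error(ssim(rand_img(8, 8), rand_img(8, 8)), "window")
})

test_that("psnr decreases as added noise variance grows", {
  ph <- make_phantom("us_like", 128, 128, seed = 2)
  ps <- vapply(c(0.001, 0.01, 0.05, 0.1), function(v) {
    psnr(ph, add_gaussian(ph, v, seed = 3))
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("the adaptive wiener baseline behaves like its local model", {
  const <- matrix(0.3, 64, 64)
  expect_equal(wiener_baseline(const), const)
  img <- rand_img(64, 64, seed = 4)
  expect_equal(wiener_baseline(img, c(1, 1)), img)
  expect_error(wiener_baseline(img, c(4, 3)), "odd")
  ph <- make_phantom("mri_like", 128, 128, seed = 5)
  noisy <- add_gaussian(ph, 0.03, seed = 6)
  expect_gt(psnr(ph, wiener_baseline(noisy)), psnr(ph, noisy))
})

test_that("summary statistics match hand-computed confidence intervals", {
  s <- summarize(c(5, 5, 5, 5))
  expect_identical(c(s$mean, s$std, s$ci_low, s$ci_high), c(5, 0, 5, 5))

  s2 <- summarize(c(1, 2, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$std, 1)
  expect_equal(c(s2$ci_low, s2$ci_high), c(0.868, 3.132), tolerance = 1e-3)

  # half-width formula at the fetal test-set size
  hw <- qnorm(0.975) * 1.23 / sqrt(252)
  expect_equal(round(hw, 2), 0.15)

  # permutation invariance and non-finite exclusion
  v <- c(4.4, 1.2, 9.9, 3.3)
  expect_identical(summarize(v), summarize(rev(v)))
  expect_message(s3 <- summarize(c(v, Inf)), "excluded")
  expect_identical(s3$mean, mean(v))
  expect_identical(s3$n_excluded, 1L)
  expect_error(summarize(c(1, Inf)), "at least 2")
  expect_error(summarize(1:3, confidence = 1), "confidence")
})
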
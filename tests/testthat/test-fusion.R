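test_that("fusion weights follow the linear-SNR proportional rule", {
  expect_equal(fusion_weights(c(30, 30))$alphas, c(0.5, 0.5))
  w <- fusion_weights(c(30, 27))$alphas
  expect_equal(w, c(0.66614, 0.33386), tolerance = 1e-4)
  expect_identical(fusion_weights(17.3)$alphas, 1)
  expect_equal(fusion_weights(rep(25, 5))$alphas, rep(0.2, 5))
})

test_that("weights are convex and strictly monotone in PSNR", {
  set.seed(3)
  for (i in 1:20) {
    ps <- runif(5, 5, 60)
    a <- fusion_weights(ps)$alphas
    expect_true(all(a >= 0))
    expect_lt(abs(sum(a) - 1), 1e-12)
    ps2 <- ps
    ps2[2] <- ps2[2] + 0.5
    expect_gt(fusion_weights(ps2)$alphas[2], a[2])
  }
})

test_that("degenerate weight inputs are rejected", {
  expect_error(fusion_weights(numeric(0)), "non-empty")
  expect_error(fusion_weights(c(30, NA)), "finite")
  expect_error(fusion_weights(c(30, Inf)), "finite")
})

test_that("fuse computes the exact pixel-wise convex combination", {
  a <- rand_img(32, 32, seed = 1)
  b <- rand_img(32, 32, seed = 2)
  w <- structure(list(alphas = c(0.7, 0.3), families = c("x", "y")),
                 class = "fusion_weights")
  expect_equal(fuse(list(a, b), w), 0.7 * a + 0.3 * b, tolerance = 1e-15)
  expect_equal(fuse(list(a, a), w), a)
  one <- structure(list(alphas = 1, families = "x"), class = "fusion_weights")
  expect_identical(fuse(list(b), one), b)
  expect_error(fuse(list(a), w), "must match")
  expect_error(fuse(list(a, rand_img(16, 16)), w), "dimensions")
})

test_that("candidates are scored, sorted, and tie-broken by family order", {
  ph <- make_phantom("us_like", 128, 128, seed = 6)
  noisy <- add_gaussian(ph, 0.01, seed = 8)
  cands <- score_candidates(ph, noisy)
  expect_length(cands, 5L)
  ps <- vapply(cands, `[[`, numeric(1), "psnr_db")
  expect_true(all(diff(ps) <= 0))
  # brute-force rescoring oracle for the top candidate
  rescored <- vapply(wavelet_families(), function(f) {
    d <- denoise_single_wavelet(noisy, f)
    10 * log10(1 / mean((ph - d)^2))
  }, numeric(1))
  expect_identical(cands[[1]]$family, names(which.max(rescored)))
  expect_equal(max(ps), max(rescored), tolerance = 1e-10)
})

test_that("hybrid selection fuses the top candidates consistently", {
  ph <- make_phantom("mri_like", 128, 128, seed = 7)
  noisy <- add_speckle(ph, 0.01, seed = 9)
  # k = 1 degenerates to the single best candidate
  h1 <- hybrid_wavelet_denoise(ph, noisy, k_select = 1)
  expect_identical(h1$image, h1$candidates[[1]]$denoised)
  expect_identical(h1$weights$alphas, 1)
  # k = 2: fused result cannot fall below the weaker selected candidate
  h2 <- hybrid_wavelet_denoise(ph, noisy, k_select = 2)
  sel_ps <- vapply(h2$candidates[1:2], `[[`, numeric(1), "psnr_db")
  expect_gte(psnr(ph, h2$image), min(sel_ps))
  expect_lt(abs(sum(h2$weights$alphas) - 1), 1e-12)
  # result does not depend on the family order supplied
  h2b <- hybrid_wavelet_denoise(ph, noisy, k_select = 2,
                                families = rev(wavelet_families()))
  expect_equal(h2b$image, h2$image, tolerance = 1e-12)
  expect_error(hybrid_wavelet_denoise(ph, noisy, k_select = 0), "k_select")
  expect_error(hybrid_wavelet_denoise(ph, noisy, k_select = 6), "k_select")
})

test_that("hybrid fusion stays within half a dB of the selected candidates", {
  for (seed in 1:3) {
    ph <- make_phantom("us_like", 128, 128, seed = seed)
    noisy <- add_gaussian(ph, 0.003, seed = seed + 10)
    h <- hybrid_wavelet_denoise(ph, noisy, k_select = 2)
    sel_ps <- vapply(h$candidates[1:2], `[[`, numeric(1), "psnr_db")
    expect_gte(psnr(ph, h$image), max(sel_ps) - 0.5)
  }
})

test_that("psnr_ssim selection ranks by equal-weight normalized scores", {
  ph <- make_phantom("xray_like", 128, 128, seed = 11)
  noisy <- add_gaussian(ph, 0.03, seed = 12)
  h <- hybrid_wavelet_denoise(ph, noisy, k_select = 2, selection = "psnr_ssim")
  cands <- score_candidates(ph, noisy, compute_ssim = TRUE)
  ps <- vapply(cands, `[[`, numeric(1), "psnr_db")
  ss <- vapply(cands, `[[`, numeric(1), "ssim")
  norm01 <- function(v) (v - min(v)) / (max(v) - min(v))
  sc <- (norm01(ps) + norm01(ss)) / 2
  best2 <- vapply(cands[order(-sc)][1:2], `[[`, character(1), "family")
  expect_setequal(h$weights$families, best2)
})
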
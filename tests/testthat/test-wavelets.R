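test_that("zero-threshold shrinkage reproduces the input (perfect reconstruction)", {
  img <- rand_img(64, 64, seed = 2)
  for (fam in wavelet_families()) {
    rec <- denoise_single_wavelet(img, fam, levels = 4L, threshold = 0)
    expect_lt(max(abs(rec - img)), 1e-8)
  }
})

test_that("multi-level transform round-trips at levels 1 to 4 and odd sizes", {
  for (fam in wavelet_families()) {
    for (lv in 1:4) {
      img <- rand_img(64, 64, seed = lv)
      expect_lt(max(abs(waverec2(wavedec2(img, fam, lv)) - img)), 1e-8)
    }
    odd <- rand_img(131, 77, seed = 9)
    expect_lt(max(abs(waverec2(wavedec2(odd, fam, 4L)) - odd)), 1e-8)
  }
})

test_that("a constant image passes through shrinkage unchanged", {
  img <- matrix(0.42, 64, 64)
  for (fam in wavelet_families()) {
    expect_lt(max(abs(denoise_single_wavelet(img, fam) - img)), 1e-8)
  }
})

test_that("every family improves PSNR on a noisy phantom", {
  ph <- make_phantom("mri_like", 256, 256, seed = 3)
  noisy <- add_gaussian(ph, 0.01, seed = 5)
  base <- psnr(ph, noisy)
  for (fam in wavelet_families()) {
    for (rule in c("universal", "bayes")) {
      expect_gt(psnr(ph, denoise_single_wavelet(noisy, fam,
                                                threshold_rule = rule)), base)
    }
  }
})

test_that("invalid inputs are rejected with informative errors", {
  img <- rand_img(64, 64)
  expect_error(denoise_single_wavelet(img, "db97"), "unsupported wavelet family")
  expect_error(wavedec2(rand_img(8, 8), "haar", 4L), "too small")
  expect_error(wavedec2(rand_img(64, 8), "db4", 4L), "too small")
})
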
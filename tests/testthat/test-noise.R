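test_that("gaussian noise has the requested moments and PSNR", {
  img <- matrix(0.5, 1000, 1000)
  out <- add_gaussian(img, 0.003, seed = 42)
  e <- out - img
  # mid-gray, small variance: clipping never triggers
  expect_lt(abs(var(as.numeric(e)) / 0.003 - 1), 0.02)
  expect_lt(abs(mean(e)), 1e-3)
  expect_lt(abs(psnr(img, out) - 10 * log10(1 / 0.003)), 0.3)
})

test_that("zero-severity corruption is the identity", {
  img <- rand_img(32, 32)
  expect_identical(add_gaussian(img, 0, seed = 1), img)
  expect_identical(add_speckle(img, 0, seed = 1), img)
  expect_identical(add_rician(img, 0, seed = 1), img)
})

test_that("speckle noise is multiplicative with the requested variance", {
  zero <- matrix(0, 64, 64)
  expect_identical(add_speckle(zero, 0.1, seed = 3), zero)
  img <- matrix(0.5, 1000, 1000)
  out <- add_speckle(img, 0.01, seed = 7)
  ratio <- (out - img) / img
  expect_lt(abs(var(as.numeric(ratio)) / 0.01 - 1), 0.02)
  # gaussian-multiplier variant has the same variance contract
  outg <- add_speckle(img, 0.01, seed = 7, multiplier = "gaussian")
  expect_lt(abs(var(as.numeric((outg - img) / img)) / 0.01 - 1), 0.02)
})

test_that("rician corruption reduces to Rayleigh noise at zero signal", {
  img <- matrix(0, 1000, 1000)
  out <- add_rician(img, 0.1, seed = 5)
  expect_lt(abs(mean(out) / (0.1 * sqrt(pi / 2)) - 1), 0.01)
})

test_that("poisson corruption is unbiased with variance mean/peak", {
  zero <- matrix(0, 64, 64)
  expect_identical(add_poisson(zero, 100, seed = 2), zero)
  img <- matrix(0.5, 1000, 1000)
  out <- add_poisson(img, 1000, seed = 9)
  expect_lt(abs(var(as.numeric(out)) / (0.5 / 1000) - 1), 0.03)
  expect_lt(abs(mean(out) - 0.5), 3 * sqrt(0.5 / 1000 / 1e6) * 2)
})

test_that("corruption is deterministic per seed and stays in range", {
  img <- rand_img(96, 96, seed = 4)
  specs <- list(noise_spec("gaussian", 0.1, 7), noise_spec("speckle", 0.1, 7),
                noise_spec("rician", 0.04, 7), noise_spec("poisson", 25, 7))
  for (sp in specs) {
    a <- corrupt(img, sp)
    b <- corrupt(img, sp)
    expect_identical(a, b)
    expect_true(all(a >= 0 & a <= 1))
    c <- corrupt(img, noise_spec(sp$kind, sp$level, 8))
    expect_false(identical(a, c))
  }
})

test_that("invalid severity parameters are rejected", {
  img <- rand_img(16, 16)
  expect_error(add_gaussian(img, -0.1), "nonnegative")
  expect_error(add_speckle(img, -1), "nonnegative")
  expect_error(add_rician(img, -0.5), "nonnegative")
  expect_error(add_poisson(img, 0), "positive")
  expect_error(noise_spec("gaussian", -2), "positive")
})

test_that("PSNR decreases monotonically across the protocol severity levels", {
  ph <- make_phantom("us_like", 128, 128, seed = 12)
  for (kind in c("gaussian", "speckle")) {
    ps <- vapply(c(0.003, 0.03, 0.1), function(v) {
      psnr(ph, corrupt(ph, noise_spec(kind, v, seed = 5)))
    }, numeric(1))
    expect_true(all(diff(ps) < 0))
  }
})

test_that("derived seeds are stable and order-independent", {
  expect_identical(derive_seed(7, 3), derive_seed(7, 3))
  expect_false(derive_seed(7, 3) == derive_seed(7, 4))
  expect_true(derive_seed(0, 0) >= 1)
  expect_lt(derive_seed(2^30, 10^6), 2^31)
})
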
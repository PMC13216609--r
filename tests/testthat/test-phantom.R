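test_that("phantom generation is deterministic for a fixed seed", {
  a <- make_phantom("us_like", 128, 128, seed = 7)
  b <- make_phantom("us_like", 128, 128, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, make_phantom("us_like", 128, 128, seed = 8)))
})

test_that("default phantoms span the dynamic range with several gray modes", {
  for (kind in c("us_like", "mri_like", "xray_like")) {
    ph <- make_phantom(kind, 256, 256, seed = 5)
    expect_true(all(ph >= 0 & ph <= 1))
    expect_gte(diff(range(ph)), 0.5)
    # number of distinct occupied gray bands (0.05-wide, >2% of pixels)
    occ <- tabulate(findInterval(ph, seq(0, 1, by = 0.05)), nbins = 21)
    expect_gte(sum(occ / length(ph) > 0.02), 5)
  }
})

test_that("a single texture-free structure yields few gray plateaus", {
  ph <- make_phantom("us_like", 256, 256, n_structures = 1,
                     texture_amplitude = 0, seed = 2)
  occ <- tabulate(findInterval(ph, seq(0, 1, by = 0.02)), nbins = 51)
  expect_lte(sum(occ / length(ph) > 0.005), 10)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(make_phantom("us_like", 64, 128), ">= 128")
  expect_error(make_phantom("us_like", 128, 128, n_structures = 0), ">= 1")
  expect_error(make_phantom("us_like", 128, 128, texture_amplitude = 0.3),
               "texture_amplitude")
  expect_error(make_dataset(0, "us_like"), ">= 1")
})

test_that("phantom corpora are reproducible, distinct, and fast to build", {
  t0 <- Sys.time()
  imgs <- make_dataset(200, "mri_like", 256, 256, seed = 3)
  dt <- as.numeric(Sys.time() - t0, units = "secs")
  # budget consistent with 1262 images in under a minute
  expect_lt(dt / 200 * 1262, 60)
  expect_length(imgs, 200L)
  expect_identical(imgs, make_dataset(200, "mri_like", 256, 256, seed = 3))
  # pairwise distinct (spot-check against the first image)
  d <- vapply(imgs[-1], function(im) max(abs(im - imgs[[1]])), numeric(1))
  expect_true(all(d > 0))
  expect_true(anyDuplicated(names(imgs)) == 0L)
})
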
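test_that("architectures match the closed-form parameter counts", {
  # independent recomputation over the layer chains
  count <- function(chain) {
    sum(vapply(seq_len(length(chain) - 1L), function(l) {
      9L * chain[l] * chain[l + 1L] + chain[l + 1L]
    }, integer(1)))
  }
  ae <- build_autoencoder()
  fu <- build_fusion()
  expect_identical(ae$param_count, count(c(1L, 64L, 32L, 16L, 32L, 64L, 1L)))
  expect_identical(ae$param_count, 47441L)
  expect_identical(fu$param_count, count(c(2L, 64L, 32L, 16L, 32L, 64L, 1L)))
  expect_identical(fu$param_count, 48017L)
  # instantiated weights carry exactly that many numbers
  m <- init_model(ae, seed = 1)
  expect_identical(sum(lengths(m$W)) + sum(lengths(m$b)), 47441L)
  m2 <- init_model(fu, seed = 1)
  expect_identical(sum(lengths(m2$W)) + sum(lengths(m2$b)), 48017L)
})

test_that("layers preserve the 64x64 spatial size and clip at inference", {
  m <- init_model(build_autoencoder(), seed = 2)
  p <- rand_img(64, 64)
  out <- denoise_patches(m, list(p))
  expect_identical(dim(out[[1]]), c(64L, 64L))
  expect_true(all(out[[1]] >= 0 & out[[1]] <= 1))
  for (l in 1:6) {
    fm <- export_feature_maps(m, p, l)
    expect_identical(dim(fm[[1]]), c(64L, 64L))
  }
})

test_that("an all-zero network maps every input to zero", {
  m <- init_model(build_autoencoder(), seed = 3)
  m$W <- lapply(m$W, function(w) w * 0)
  out <- denoise_patches(m, list(rand_img(64, 64), matrix(1, 64, 64)))
  expect_identical(out[[1]], matrix(0, 64, 64))
  expect_identical(out[[2]], matrix(0, 64, 64))
})

test_that("training reduces the loss on an identity task", {
  patches <- lapply(1:64, function(i) rand_img(32, 32, seed = i))
  m <- init_model(build_autoencoder(), seed = 4)
  m <- train(m, patches, patches, hw_train_config(epochs = 10, seed = 5))
  expect_length(m$loss_history, 10L)
  expect_lt(m$loss_history[10], m$loss_history[1])
})

test_that("training is deterministic for a fixed seed", {
  patches <- lapply(1:16, function(i) rand_img(32, 32, seed = i))
  targets <- lapply(1:16, function(i) rand_img(32, 32, seed = 100 + i))
  run <- function() {
    m <- init_model(build_autoencoder(), seed = 6)
    train(m, patches, targets, hw_train_config(epochs = 3, batch_size = 8,
                                               seed = 7))$loss_history
  }
  a <- run(); b <- run()
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("inference is deterministic and order-preserving", {
  m <- init_model(build_autoencoder(), seed = 8)
  p <- rand_img(64, 64, seed = 9)
  out <- denoise_patches(m, list(p, p, p))
  expect_identical(out[[1]], out[[2]])
  expect_identical(out[[2]], out[[3]])
  expect_identical(denoise_patches(m, list(p)), denoise_patches(m, list(p)))
  expect_identical(denoise_patches(m, list()), list())
})

test_that("shape and configuration violations are rejected", {
  m <- init_model(build_fusion(), seed = 10)
  expect_error(denoise_patches(m, list(rand_img(64, 64))), "expected 64x64x2")
  ae <- init_model(build_autoencoder(), seed = 10)
  expect_error(train(ae, list(), list(), hw_train_config()), "empty")
  p <- list(rand_img(64, 64))
  expect_error(train(ae, p, list(), hw_train_config()), "equal length")
  expect_error(hw_train_config(epochs = 0), "epochs")
  expect_error(hw_train_config(batch_size = 0), "batch_size")
  expect_error(hw_train_config(learning_rate = -1), "learning_rate")
})

test_that("feature-map export returns one map per filter", {
  m <- init_model(build_autoencoder(), seed = 11)
  p <- rand_img(64, 64, seed = 12)
  expect_length(export_feature_maps(m, p, 3), 16L)
  expect_length(export_feature_maps(m, p, 5), 64L)
  expect_length(export_feature_maps(m, p, 6), 1L)
  expect_error(export_feature_maps(m, p, 7), "between 1 and 6")
  expect_error(export_feature_maps(m, p, 0), "between 1 and 6")
})

test_that("the same-padded convolution matches a direct spatial oracle", {
  # one 3x3 conv layer, random weights, zero-padding semantics
  m <- init_model(build_autoencoder(), seed = 13)
  p <- rand_img(16, 16, seed = 14)
  a <- export_feature_maps(m, p, 1)
  conv_oracle <- function(x, w3, bias) {
    h <- nrow(x); w <- ncol(x)
    xp <- matrix(0, h + 2, w + 2)
    xp[2:(h + 1), 2:(w + 1)] <- x
    out <- matrix(bias, h, w)
    for (dy in -1:1) for (dx in -1:1) {
      k <- (dx + 1) * 3 + (dy + 1) + 1  # offset enumeration, column-major
      out <- out + w3[k] * xp[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
    }
    pmax(out, 0)
  }
  for (f in c(1, 17, 64)) {
    expect_equal(a[[f]], conv_oracle(p, m$W[[1]][f, ], m$b[[1]][f]),
                 tolerance = 1e-5)
  }
})

test_that("autoencoder training beats the noisy baseline on phantoms", {
  imgs <- make_dataset(64, "us_like", 128, 128, seed = 21)
  noise <- noise_spec("speckle", 0.03, seed = 22)
  noisy <- lapply(seq_along(imgs), function(i) {
    corrupt(imgs[[i]], noise_spec("speckle", 0.03, derive_seed(22, i)))
  })
  split <- split_dataset(names(imgs), 0.8, seed = 23)
  tr <- match(split$train_ids, names(imgs))
  te <- match(split$test_ids, names(imgs))
  pin <- unlist(lapply(tr, function(i) extract_patches(noisy[[i]], 64)$patches),
                recursive = FALSE)
  ptg <- unlist(lapply(tr, function(i) extract_patches(imgs[[i]], 64)$patches),
                recursive = FALSE)
  m <- init_model(build_autoencoder(), seed = 24)
  m <- train(m, pin, ptg, hw_train_config(epochs = 10, batch_size = 16,
                                          seed = 25))
  tin <- unlist(lapply(te, function(i) extract_patches(noisy[[i]], 64)$patches),
                recursive = FALSE)
  ttg <- unlist(lapply(te, function(i) extract_patches(imgs[[i]], 64)$patches),
                recursive = FALSE)
  out <- denoise_patches(m, tin)
  noisy_psnr <- mean(mapply(psnr, ttg, tin))
  ae_psnr <- mean(mapply(psnr, ttg, out))
  expect_gt(ae_psnr, noisy_psnr)
})
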
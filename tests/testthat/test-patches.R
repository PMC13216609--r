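test_that("tiling geometry matches ceiling arithmetic", {
  pe <- extract_patches(rand_img(128, 128), 64)
  expect_length(pe$patches, 4L)
  expect_identical(pe$grid$pad_bottom, 0L)
  expect_identical(pe$grid$pad_right, 0L)

  pe2 <- extract_patches(rand_img(130, 70), 64)
  expect_identical(pe2$grid$rows, 3L)
  expect_identical(pe2$grid$cols, 2L)
  expect_identical(pe2$grid$pad_bottom, 62L)
  expect_identical(pe2$grid$pad_right, 58L)
  expect_length(pe2$patches, 6L)

  img <- rand_img(64, 64)
  pe3 <- extract_patches(img, 64)
  expect_length(pe3$patches, 1L)
  expect_identical(pe3$patches[[1]], img)

  expect_error(extract_patches(img, 4), "patch_size")
})

test_that("extraction and reassembly round-trip bit-identically", {
  sizes <- list(c(64, 64), c(130, 70), c(540, 800), c(512, 512))
  for (ps in c(32L, 64L, 128L)) {
    for (s in sizes) {
      if (min(s) < ps / 2) next  # mirror padding needs pad <= image size
      img <- rand_img(s[1], s[2], seed = ps + s[1])
      pe <- extract_patches(img, ps)
      expect_identical(reassemble(pe$patches, pe$grid), img)
    }
  }
})

test_that("patch placement is order-sensitive and coverage exact", {
  img <- rand_img(200, 300, seed = 5)
  pe <- extract_patches(img, 64)
  expect_identical(sum(lengths(pe$patches)),
                   pe$grid$rows * pe$grid$cols * 64L * 64L)
  zeros <- lapply(pe$patches, function(p) p * 0)
  expect_identical(reassemble(zeros, pe$grid), matrix(0, 200, 300))
  perm <- pe$patches[c(2:length(pe$patches), 1)]
  expect_false(identical(reassemble(perm, pe$grid), img))
  expect_error(reassemble(pe$patches[-1], pe$grid), "expected")
})

test_that("image-level split is deterministic, disjoint and sized by rounding", {
  ids <- sprintf("im%03d", 1:10)
  s <- split_dataset(ids, 0.8, seed = 3)
  expect_length(s$train_ids, 8L)
  expect_length(s$test_ids, 2L)
  expect_length(intersect(s$train_ids, s$test_ids), 0L)
  expect_setequal(c(s$train_ids, s$test_ids), ids)
  expect_identical(split_dataset(ids, 0.8, seed = 3), s)
  expect_false(identical(split_dataset(ids, 0.8, seed = 4)$train_ids,
                         s$train_ids))

  big <- split_dataset(seq_len(1262), 0.8, seed = 1)
  expect_length(big$train_ids, 1010L)
  expect_length(big$test_ids, 252L)

  expect_error(split_dataset("only_one"), "at least 2")
  expect_error(split_dataset(ids, 1.2), "between 0 and 1")
})

test_that("the leakage guard trips on contaminated patch parents", {
  s <- split_dataset(letters[1:10], 0.8, seed = 1)
  ok <- c(rep(s$train_ids[1], 4), rep(s$test_ids[1], 4))
  expect_true(assert_no_leakage(ok, s))
  bad <- structure(list(train_ids = c("a", "b"), test_ids = c("b", "c")),
                   class = "split_spec")
  expect_error(assert_no_leakage(c("a", "b"), bad), "both sides")
})
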
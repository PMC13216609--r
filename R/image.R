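#' Grayscale image utilities
#'
#' Throughout the package a grayscale image is an ordinary numeric matrix with
#' intensities on the normalized \[0, 1\] scale. `as_gray()` coerces and
#' validates such a matrix; `clip01()` clamps values into range.
#'
#' @param img numeric matrix of intensities.
#' @param min_dim minimum height/width accepted.
#' @return `as_gray()` returns the validated matrix.
#' @examples
#' img <- as_gray(matrix(runif(64), 8, 8))
#' range(clip01(img + 0.5))
#' @export
as_gray <- function(img, min_dim = 1L) {
  if (is.data.frame(img)) img <- as.matrix(img)
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop(sprintf("image must be at least %dx%d", min_dim, min_dim), call. = FALSE)
  }
  if (!all(is.finite(img))) stop("image contains non-finite values", call. = FALSE)
  if (min(img) < 0 || max(img) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  img
}

#' @rdname as_gray
#' @param x numeric vector or matrix.
#' @export
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

.assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
}

#' Read and write grayscale images
#'
#' Images are read from PNG or TIFF (8- or 16-bit) and normalized to \[0, 1\]
#' by the reading library; multi-channel files are collapsed to grayscale by
#' channel averaging. `write_gray()` writes 8-bit PNG or 16-bit TIFF depending
#' on the file extension.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param img numeric matrix in \[0, 1\].
#' @return `read_gray()` returns a numeric matrix in \[0, 1\].
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(x)) == 3L) {
    nch <- dim(x)[3]
    # drop alpha, average color channels
    ch <- min(nch, 3L)
    x <- apply(x[, , seq_len(ch), drop = FALSE], c(1, 2), mean)
  }
  as_gray(clip01(x))
}

#' @rdname read_gray
#' @export
write_gray <- function(img, path) {
  img <- as_gray(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, target = path),
    tif = ,
    tiff = tiff::writeTIFF(img, where = path, bits.per.sample = 16L),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' Absolute difference map between two images
#'
#' Used for error-map visualisation of a denoised result against its
#' reference. The raw absolute differences are returned; with
#' `stretch = TRUE` the map is linearly rescaled to use the full \[0, 1\]
#' range for display (the raw map is attached as attribute `"raw"`).
#'
#' @param reference,test images of identical shape.
#' @param stretch contrast-stretch the map for display.
#' @return numeric matrix of absolute differences.
#' @export
difference_map <- function(reference, test, stretch = FALSE) {
  reference <- as_gray(reference)
  test <- as_gray(test)
  .assert_same_shape(reference, test)
  m <- abs(reference - test)
  if (stretch) {
    raw <- m
    rng <- max(m)
    if (rng > 0) m <- m / rng
    attr(m, "raw") <- raw
  }
  m
}
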
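#' Non-overlapping patch extraction
#'
#' Tiles an image into non-overlapping square patches. If the image
#' dimensions are not multiples of the patch size, the image is first
#' reflection-padded (mirror including the edge row/column) on the bottom and
#' right; the returned grid records the padding so that [reassemble()]
#' reverses the operation exactly. Patches are emitted row-major from the
#' top-left tile.
#'
#' @param img grayscale image matrix.
#' @param patch_size side length of the square patches (>= 8).
#' @return list with `patches` (list of matrices) and `grid` (a
#'   `"patch_grid"` with tile counts, padding and original size).
#' @examples
#' pe <- extract_patches(matrix(runif(130 * 70), 130, 70), 64)
#' pe$grid$rows * pe$grid$cols  # 6 patches
#' @export
extract_patches <- function(img, patch_size = 64L) {
  img <- as_gray(img)
  patch_size <- as.integer(patch_size)
  if (patch_size < 8L) stop("patch_size must be >= 8", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  rows <- as.integer(ceiling(h / patch_size))
  cols <- as.integer(ceiling(w / patch_size))
  pad_bottom <- rows * patch_size - h
  pad_right <- cols * patch_size - w
  if (pad_bottom > h || pad_right > w) {
    stop("image too small to mirror-pad to the patch size", call. = FALSE)
  }
  padded <- img
  if (pad_bottom > 0) {
    padded <- rbind(padded, padded[h:(h - pad_bottom + 1L), , drop = FALSE])
  }
  if (pad_right > 0) {
    padded <- cbind(padded, padded[, w:(w - pad_right + 1L), drop = FALSE])
  }
  grid <- structure(list(patch_size = patch_size, rows = rows, cols = cols,
                         pad_bottom = pad_bottom, pad_right = pad_right,
                         original_height = h, original_width = w),
                    class = "patch_grid")
  patches <- vector("list", rows * cols)
  k <- 1L
  for (r in seq_len(rows)) {
    ri <- ((r - 1L) * patch_size + 1L):(r * patch_size)
    for (cl in seq_len(cols)) {
      ci <- ((cl - 1L) * patch_size + 1L):(cl * patch_size)
      patches[[k]] <- padded[ri, ci]
      k <- k + 1L
    }
  }
  list(patches = patches, grid = grid)
}

#' Reassemble patches into the original image
#'
#' Inverse of [extract_patches()]: places the patches row-major onto the
#' padded canvas and crops the padding. Because the tiling is non-overlapping
#' no averaging or blending is involved and the round trip is bit-identical.
#'
#' @param patches list of patch matrices.
#' @param grid the `"patch_grid"` returned by [extract_patches()].
#' @return image matrix of the original size.
#' @export
reassemble <- function(patches, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  if (length(patches) != grid$rows * grid$cols) {
    stop(sprintf("expected %d patches, got %d", grid$rows * grid$cols,
                 length(patches)), call. = FALSE)
  }
  ps <- grid$patch_size
  canvas <- matrix(0, grid$rows * ps, grid$cols * ps)
  k <- 1L
  for (r in seq_len(grid$rows)) {
    ri <- ((r - 1L) * ps + 1L):(r * ps)
    for (cl in seq_len(grid$cols)) {
      ci <- ((cl - 1L) * ps + 1L):(cl * ps)
      p <- patches[[k]]
      if (!identical(dim(p), c(ps, ps))) {
        stop("patch ", k, " does not match the grid patch size", call. = FALSE)
      }
      canvas[ri, ci] <- p
      k <- k + 1L
    }
  }
  canvas[seq_len(grid$original_height), seq_len(grid$original_width), drop = FALSE]
}

#' Image-level train/test split
#'
#' Deterministic shuffled split of image identifiers. Splitting happens at
#' the image level before any patch extraction, so no image can contribute
#' patches to both sides (the leakage guard of patch-based training).
#'
#' @param image_ids character or integer vector of unique image identifiers.
#' @param fraction fraction of images assigned to training (0 < f < 1);
#'   the train count is `round(fraction * N)`, clamped so both sides are
#'   non-empty.
#' @param seed integer seed; the same seed always yields the same split.
#' @return a `"split_spec"` list with `train_ids`, `test_ids`,
#'   `train_fraction` and `seed`.
#' @export
split_dataset <- function(image_ids, fraction = 0.8, seed = 0L) {
  n <- length(image_ids)
  if (n < 2L) stop("need at least 2 images to split", call. = FALSE)
  if (anyDuplicated(image_ids)) stop("image_ids must be unique", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_train <- min(max(round(fraction * n), 1L), n - 1L)
  structure(list(train_ids = image_ids[sort(perm[seq_len(n_train)])],
                 test_ids = image_ids[sort(perm[(n_train + 1L):n])],
                 train_fraction = fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Assert that patch-level samples do not leak across the split
#'
#' @param parent_ids vector of parent image ids, one per patch sample.
#' @param split a `"split_spec"`.
#' @return invisibly `TRUE`; errors if any parent id occurs on both sides.
#' @export
assert_no_leakage <- function(parent_ids, split) {
  stopifnot(inherits(split, "split_spec"))
  both <- intersect(split$train_ids, split$test_ids)
  if (length(both)) stop("split is invalid: ids on both sides", call. = FALSE)
  tr <- unique(parent_ids[parent_ids %in% split$train_ids])
  te <- unique(parent_ids[parent_ids %in% split$test_ids])
  if (length(intersect(tr, te))) {
    stop("patch-level leakage: a parent image contributes to train and test",
         call. = FALSE)
  }
  invisible(TRUE)
}
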
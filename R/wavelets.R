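# Two-dimensional discrete wavelet transform with symmetric (half-point)
# boundary extension, decimated, multi-level. Filter banks are the standard
# published coefficient sets for the five supported families. Coefficients
# are stored to full double precision; biorthogonal families carry distinct
# decomposition and reconstruction filters.

.hw_filters <- list(
  haar = list(
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    rec_lo = c(0.7071067811865476, 0.7071067811865476),
    rec_hi = c(0.7071067811865476, -0.7071067811865476)
  ),
  db4 = list(
    dec_lo = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
               -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
               0.7148465705529157, 0.2303778133088965),
    dec_hi = c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
               -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
               -0.0328830116668852, -0.010597401785069032),
    rec_lo = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
               -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
               0.0328830116668852, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.0328830116668852, 0.030841381835560764,
               0.18703481171909309, -0.027983769416859854, -0.6308807679298589,
               0.7148465705529157, -0.2303778133088965)
  ),
  sym4 = list(
    dec_lo = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
               0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
               -0.012603967262037833, 0.0322231006040427),
    dec_hi = c(-0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
               0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
               0.02963552764599851, -0.07576571478927333),
    rec_lo = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
               0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
               -0.02963552764599851, -0.07576571478927333),
    rec_hi = c(-0.07576571478927333, 0.02963552764599851, 0.49761866763201545,
               -0.8037387518059161, 0.29785779560527736, 0.09921954357684722,
               -0.012603967262037833, -0.0322231006040427)
  ),
  coif2 = list(
    dec_lo = c(-0.000720549445520347, -0.0018232088709110323, 0.005611434819368834,
               0.02368017194684777, -0.05943441864643109, -0.07648859907828076,
               0.4170051844232391, 0.8127236354494135, 0.3861100668227629,
               -0.0673725547237256, -0.04146493678687178, 0.01638733646320364),
    dec_hi = c(-0.01638733646320364, -0.04146493678687178, 0.0673725547237256,
               0.3861100668227629, -0.8127236354494135, 0.4170051844232391,
               0.07648859907828076, -0.05943441864643109, -0.02368017194684777,
               0.005611434819368834, 0.0018232088709110323, -0.000720549445520347),
    rec_lo = c(0.01638733646320364, -0.04146493678687178, -0.0673725547237256,
               0.3861100668227629, 0.8127236354494135, 0.4170051844232391,
               -0.07648859907828076, -0.05943441864643109, 0.02368017194684777,
               0.005611434819368834, -0.0018232088709110323, -0.000720549445520347),
    rec_hi = c(-0.000720549445520347, 0.0018232088709110323, 0.005611434819368834,
               -0.02368017194684777, -0.05943441864643109, 0.07648859907828076,
               0.4170051844232391, -0.8127236354494135, 0.3861100668227629,
               0.0673725547237256, -0.04146493678687178, -0.01638733646320364)
  ),
  `bior3.3` = list(
    dec_lo = c(0.06629126073623882, -0.1988737822087165, -0.15467960838455727,
               0.9943689110435825, 0.9943689110435825, -0.15467960838455727,
               -0.1988737822087165, 0.06629126073623882),
    dec_hi = c(0, 0, -0.1767766952966369, 0.5303300858899106,
               -0.5303300858899106, 0.1767766952966369, 0, 0),
    rec_lo = c(0, 0, 0.1767766952966369, 0.5303300858899106,
               0.5303300858899106, 0.1767766952966369, 0, 0),
    rec_hi = c(0.06629126073623882, 0.1988737822087165, -0.15467960838455727,
               -0.9943689110435825, 0.9943689110435825, 0.15467960838455727,
               -0.1988737822087165, -0.06629126073623882)
  )
)

#' Supported wavelet families
#'
#' The five families used by the wavelet branch, in the fixed order that also
#' breaks ties during candidate selection.
#'
#' @return character vector of family names.
#' @export
wavelet_families <- function() c("sym4", "db4", "bior3.3", "coif2", "haar")

.get_filters <- function(family) {
  f <- .hw_filters[[family]]
  if (is.null(f)) {
    stop("unsupported wavelet family: ", family,
         " (supported: ", paste(names(.hw_filters), collapse = ", "), ")",
         call. = FALSE)
  }
  f
}

# decimated analysis filtering of every column (along the row index):
# symmetric (half-point) extension, convolution, downsample by 2 with
# offset 2; the kernel lives in compiled code
.dwt_rows <- function(x, filt) cpp_dwt_rows(x, filt)

# synthesis along the row index: upsample both coefficient sets, filter
# with the reconstruction pair, crop the boundary surplus, trim to n_out
.idwt_rows <- function(a, d, rec_lo, rec_hi, n_out) {
  cpp_idwt_rows(a, d, rec_lo, rec_hi, as.integer(n_out))
}

.dwt2_step <- function(x, f) {
  lo <- .dwt_rows(x, f$dec_lo)
  hi <- .dwt_rows(x, f$dec_hi)
  list(
    LL = t(.dwt_rows(t(lo), f$dec_lo)),
    LH = t(.dwt_rows(t(hi), f$dec_lo)),
    HL = t(.dwt_rows(t(lo), f$dec_hi)),
    HH = t(.dwt_rows(t(hi), f$dec_hi))
  )
}

.idwt2_step <- function(bands, f, dims) {
  lo <- t(.idwt_rows(t(bands$LL), t(bands$HL), f$rec_lo, f$rec_hi, dims[2]))
  hi <- t(.idwt_rows(t(bands$LH), t(bands$HH), f$rec_lo, f$rec_hi, dims[2]))
  .idwt_rows(lo, hi, f$rec_lo, f$rec_hi, dims[1])
}

#' Multi-level 2-D wavelet decomposition and reconstruction
#'
#' `wavedec2()` decomposes an image into `levels` scales of detail sub-bands
#' (LH, HL, HH) plus a final approximation band, using decimated filtering
#' with symmetric boundary extension. `waverec2()` inverts it exactly
#' (perfect reconstruction up to floating-point rounding).
#'
#' @param img numeric matrix.
#' @param family one of [wavelet_families()].
#' @param levels number of decomposition scales.
#' @return `wavedec2()`: a list with the approximation matrix `approx`, a
#'   list `detail` of per-level sub-band lists (finest first), and bookkeeping
#'   needed for inversion.
#' @export
wavedec2 <- function(img, family, levels = 4L) {
  if (!is.matrix(img) || !is.numeric(img)) stop("img must be a numeric matrix", call. = FALSE)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  if (min(dim(img)) < 2^levels) {
    stop(sprintf("image of size %dx%d too small for %d decomposition levels",
                 nrow(img), ncol(img), levels), call. = FALSE)
  }
  f <- .get_filters(family)
  detail <- vector("list", levels)
  dims <- vector("list", levels)
  cur <- img
  for (l in seq_len(levels)) {
    dims[[l]] <- dim(cur)
    s <- .dwt2_step(cur, f)
    detail[[l]] <- s[c("LH", "HL", "HH")]
    cur <- s$LL
  }
  structure(list(approx = cur, detail = detail, dims = dims,
                 family = family, levels = levels),
            class = "wavedec2")
}

#' @rdname wavedec2
#' @param dec a `"wavedec2"` object.
#' @export
waverec2 <- function(dec) {
  stopifnot(inherits(dec, "wavedec2"))
  f <- .get_filters(dec$family)
  cur <- dec$approx
  for (l in rev(seq_len(dec$levels))) {
    bands <- dec$detail[[l]]
    bands$LL <- cur
    cur <- .idwt2_step(bands, f, dec$dims[[l]])
  }
  cur
}

.soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# robust noise-sd estimate from the finest diagonal sub-band
.noise_sd_mad <- function(dec) {
  median(abs(dec$detail[[1]]$HH)) / 0.6745
}

#' Wavelet shrinkage denoising with a single family
#'
#' Forward multi-level DWT, soft thresholding of all detail sub-bands (the
#' approximation band is left untouched), inverse transform and clipping to
#' \[0, 1\]. The noise standard deviation is estimated from the finest
#' diagonal sub-band by the median absolute deviation (MAD / 0.6745).
#'
#' Two shrinkage rules are available: `"universal"` applies the universal
#' threshold `sigma * sqrt(2 log N)` (N = number of pixels) to every detail
#' sub-band; `"bayes"` applies the BayesShrink rule, a per-sub-band threshold
#' `sigma^2 / sigma_x` where `sigma_x` is the estimated signal standard
#' deviation of that band.
#'
#' @param noisy grayscale image matrix in \[0, 1\].
#' @param family one of [wavelet_families()].
#' @param levels decomposition depth (default 4).
#' @param threshold_rule `"universal"` or `"bayes"`.
#' @param threshold optional fixed threshold overriding the rule (0 disables
#'   shrinkage entirely, returning the perfect reconstruction).
#' @return denoised image in \[0, 1\].
#' @export
denoise_single_wavelet <- function(noisy, family, levels = 4L,
                                   threshold_rule = c("universal", "bayes"),
                                   threshold = NULL) {
  noisy <- as_gray(noisy)
  threshold_rule <- match.arg(threshold_rule)
  dec <- wavedec2(noisy, family, levels)
  sig <- .noise_sd_mad(dec)
  n_pix <- length(noisy)
  for (l in seq_len(dec$levels)) {
    for (b in c("LH", "HL", "HH")) {
      band <- dec$detail[[l]][[b]]
      t <- if (!is.null(threshold)) {
        threshold
      } else if (threshold_rule == "universal") {
        sig * sqrt(2 * log(n_pix))
      } else {
        sx2 <- max(mean(band^2) - sig^2, 0)
        if (sx2 > 0) sig^2 / sqrt(sx2) else max(abs(band))
      }
      dec$detail[[l]][[b]] <- .soft_threshold(band, t)
    }
  }
  clip01(waverec2(dec))
}
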
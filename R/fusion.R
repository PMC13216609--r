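#' PSNR-proportional fusion weights
#'
#' Converts per-candidate PSNR scores (dB) into convex combination weights:
#' each weight is the candidate's linear-scale signal-to-noise ratio
#' `10^(PSNR/10)` normalized by the sum over all candidates. Weights are
#' nonnegative, sum to one, and increase strictly with the candidate's PSNR.
#'
#' @param psnrs_db numeric vector of PSNR scores in dB (finite).
#' @param families optional character vector naming the candidates.
#' @return object of class `"fusion_weights"` with elements `alphas` and
#'   `families`, in the input order.
#' @examples
#' fusion_weights(c(30, 27))
#' @export
fusion_weights <- function(psnrs_db, families = NULL) {
  if (length(psnrs_db) == 0L) stop("psnrs_db must be non-empty", call. = FALSE)
  if (!is.numeric(psnrs_db) || !all(is.finite(psnrs_db))) {
    stop("all PSNR values must be finite numbers", call. = FALSE)
  }
  # subtract the maximum before exponentiating so large dB values cannot overflow
  s <- 10^((psnrs_db - max(psnrs_db)) / 10)
  alphas <- s / sum(s)
  if (is.null(families)) families <- rep(NA_character_, length(alphas))
  structure(list(alphas = alphas, families = families), class = "fusion_weights")
}

#' Fuse denoised candidates by convex combination
#'
#' Pixel-wise weighted sum of candidate images with the weights of
#' [fusion_weights()]. Since the weights are convex and the candidates lie
#' in \[0, 1\], so does the fused image.
#'
#' @param candidates list of wavelet candidates (see [score_candidates()]) or
#'   plain image matrices, all of identical shape.
#' @param weights a `"fusion_weights"` object with one weight per candidate.
#' @return fused image matrix.
#' @export
fuse <- function(candidates, weights) {
  stopifnot(inherits(weights, "fusion_weights"))
  imgs <- lapply(candidates, function(ci) {
    if (inherits(ci, "wavelet_candidate")) ci$denoised else ci
  })
  if (length(imgs) != length(weights$alphas)) {
    stop("number of candidates must match number of weights", call. = FALSE)
  }
  d <- dim(imgs[[1]])
  for (im in imgs) {
    if (!identical(dim(im), d)) stop("candidate images must share dimensions", call. = FALSE)
  }
  out <- matrix(0, d[1], d[2])
  for (k in seq_along(imgs)) out <- out + weights$alphas[k] * imgs[[k]]
  clip01(out)
}

#' Score wavelet denoising candidates against a reference
#'
#' Runs [denoise_single_wavelet()] for every requested family and scores the
#' result by PSNR (and SSIM) against the reference image. The returned list
#' is sorted by decreasing PSNR; exact ties fall back to the fixed family
#' order `sym4 > db4 > bior3.3 > coif2 > haar`.
#'
#' @param reference clean (or pseudo-reference) image.
#' @param noisy corrupted image of the same shape.
#' @param families character vector of families to evaluate.
#' @param levels,threshold_rule passed to [denoise_single_wavelet()].
#' @param compute_ssim also score SSIM (needed for `selection = "psnr_ssim"`).
#' @return list of `"wavelet_candidate"` objects with fields `family`,
#'   `denoised`, `psnr_db`, `ssim`, `levels`.
#' @export
score_candidates <- function(reference, noisy, families = wavelet_families(),
                             levels = 4L,
                             threshold_rule = c("universal", "bayes"),
                             compute_ssim = FALSE) {
  reference <- as_gray(reference)
  noisy <- as_gray(noisy)
  .assert_same_shape(reference, noisy)
  threshold_rule <- match.arg(threshold_rule)
  cands <- lapply(families, function(fam) {
    den <- denoise_single_wavelet(noisy, fam, levels, threshold_rule)
    structure(list(family = fam,
                   denoised = den,
                   psnr_db = psnr(reference, den),
                   ssim = if (compute_ssim) ssim(reference, den) else NA_real_,
                   levels = levels),
              class = "wavelet_candidate")
  })
  psnrs <- vapply(cands, `[[`, numeric(1), "psnr_db")
  tie <- match(vapply(cands, `[[`, character(1), "family"), wavelet_families())
  cands[order(-psnrs, tie)]
}

#' Hybrid wavelet denoising: select and fuse the best families
#'
#' The wavelet branch of the hybrid pipeline: every candidate family denoises the full
#' image, the top `k_select` candidates under the chosen selection criterion
#' are retained, and their outputs are fused pixel-wise with
#' PSNR-proportional weights.
#'
#' Selection criteria: `"psnr"` ranks candidates by PSNR alone;
#' `"psnr_ssim"` ranks by the mean of min-max-normalized PSNR and SSIM
#' across the candidate set (equal weighting). In both cases the fusion
#' weights themselves are computed from the selected candidates' PSNRs.
#'
#' @param reference reference image for scoring (the clean image during
#'   synthetic evaluation; a pseudo-reference such as the autoencoder output
#'   in blind mode).
#' @param noisy corrupted image.
#' @param k_select number of candidates to fuse (1 to number of families).
#' @param selection `"psnr"` or `"psnr_ssim"`.
#' @inheritParams score_candidates
#' @return list with the fused image (`image`), the `"fusion_weights"`
#'   (`weights`) and the full sorted candidate list (`candidates`).
#' @export
hybrid_wavelet_denoise <- function(reference, noisy, k_select = 2L,
                                   selection = c("psnr", "psnr_ssim"),
                                   families = wavelet_families(),
                                   levels = 4L,
                                   threshold_rule = c("universal", "bayes")) {
  selection <- match.arg(selection)
  threshold_rule <- match.arg(threshold_rule)
  k_select <- as.integer(k_select)
  if (k_select < 1L || k_select > length(families)) {
    stop("k_select must be between 1 and the number of families", call. = FALSE)
  }
  cands <- score_candidates(reference, noisy, families, levels, threshold_rule,
                            compute_ssim = (selection == "psnr_ssim"))
  if (selection == "psnr_ssim") {
    ps <- vapply(cands, `[[`, numeric(1), "psnr_db")
    ss <- vapply(cands, `[[`, numeric(1), "ssim")
    norm01 <- function(v) {
      fin <- v[is.finite(v)]
      r <- range(fin)
      if (diff(r) == 0) return(rep(0.5, length(v)))
      pmin(pmax((v - r[1]) / diff(r), 0), 1)
    }
    score <- (norm01(ps) + norm01(ss)) / 2
    tie <- match(vapply(cands, `[[`, character(1), "family"), wavelet_families())
    cands <- cands[order(-score, tie)]
  }
  sel <- cands[seq_len(k_select)]
  ps <- vapply(sel, `[[`, numeric(1), "psnr_db")
  fams <- vapply(sel, `[[`, character(1), "family")
  if (any(is.infinite(ps))) {
    # a candidate that reproduces the reference exactly: split weight
    # uniformly over the exact candidates
    a <- as.numeric(is.infinite(ps))
    w <- structure(list(alphas = a / sum(a), families = fams),
                   class = "fusion_weights")
  } else {
    w <- fusion_weights(ps, fams)
  }
  list(image = fuse(sel, w), weights = w, candidates = cands)
}
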
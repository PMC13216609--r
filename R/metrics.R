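#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels on the normalized intensity scale
#' (peak 1 by default, which yields the same dB values as peak 255 on 8-bit
#' integers). Identical images have zero MSE and return `Inf` as the
#' "identical" sentinel; callers that aggregate PSNR should treat infinite
#' values explicitly (see [summarize()]).
#'
#' @param reference,test images of identical shape.
#' @param peak peak intensity value (default 1).
#' @return PSNR in dB, possibly `Inf`.
#' @examples
#' a <- matrix(0.2, 16, 16)
#' psnr(a, a + 0.1)  # exactly 20 dB
#' @export
psnr <- function(reference, test, peak = 1) {
  if (!identical(dim(reference), dim(test))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# separable valid-region filtering with an outer-product kernel k %o% k
.filter2_valid <- function(x, k) {
  p <- length(k)
  n <- nrow(x) - p + 1L
  m <- ncol(x) - p + 1L
  tmp <- matrix(0, n, ncol(x))
  for (j in seq_len(p)) tmp <- tmp + k[j] * x[j:(j + n - 1L), , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_len(p)) out <- out + k[j] * tmp[, j:(j + m - 1L), drop = FALSE]
  out
}

#' Structural similarity index (SSIM)
#'
#' Mean local structural similarity with the standard configuration: an
#' 11x11 Gaussian window (sigma 1.5), stabilizing constants
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with `K1 = 0.01`, `K2 = 0.03` and
#' dynamic range `L = 1`. Local statistics are computed over the valid
#' interior (no boundary padding) and the map is averaged.
#'
#' @param reference,test images of identical shape, min dimension >= window.
#' @param window window side length (odd).
#' @param sigma Gaussian window standard deviation in pixels.
#' @param K1,K2 stabilizer coefficients.
#' @param L dynamic range of the data.
#' @return scalar in \[-1, 1\]; 1 for identical images.
#' @export
ssim <- function(reference, test, window = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03, L = 1) {
  if (!identical(dim(reference), dim(test))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  if (min(dim(reference)) < window) {
    stop("image smaller than the SSIM window", call. = FALSE)
  }
  r <- (window - 1) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  mu1 <- .filter2_valid(reference, k)
  mu2 <- .filter2_valid(test, k)
  s11 <- .filter2_valid(reference * reference, k) - mu1 * mu1
  s22 <- .filter2_valid(test * test, k) - mu2 * mu2
  s12 <- .filter2_valid(reference * test, k) - mu1 * mu2
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

# box-filter local sums with replicate padding
.local_mean <- function(x, wr, wc) {
  rr <- (wr - 1L) %/% 2L
  rc <- (wc - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  xp <- x[pmin(pmax(seq_len(n + 2L * rr) - rr, 1L), n),
          pmin(pmax(seq_len(m + 2L * rc) - rc, 1L), m), drop = FALSE]
  tmp <- matrix(0, n, m + 2L * rc)
  for (j in seq_len(wr)) tmp <- tmp + xp[j:(j + n - 1L), , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_len(wc)) out <- out + tmp[, j:(j + m - 1L), drop = FALSE]
  out / (wr * wc)
}

#' Locally adaptive Wiener filter baseline
#'
#' Classical pixel-wise adaptive Wiener filtering: in each local window the
#' mean and variance are estimated (replicate boundary padding), the noise
#' variance is estimated as the mean of all local variances, and the output
#' is `m + max(v - noise, 0) / v * (x - m)`. Constant images (and 1x1
#' windows) pass through unchanged.
#'
#' @param noisy grayscale image matrix.
#' @param window integer pair of odd window dimensions (default 3x3).
#' @return filtered image clipped to \[0, 1\].
#' @export
wiener_baseline <- function(noisy, window = c(3L, 3L)) {
  noisy <- as_gray(noisy)
  window <- as.integer(rep(window, length.out = 2L))
  if (any(window < 1L) || any(window %% 2L == 0L)) {
    stop("window dimensions must be odd positive integers", call. = FALSE)
  }
  m <- .local_mean(noisy, window[1], window[2])
  v <- pmax(.local_mean(noisy * noisy, window[1], window[2]) - m * m, 0)
  noise <- mean(v)
  gain <- ifelse(v > noise, (v - noise) / v, 0)
  clip01(m + gain * (noisy - m))
}

#' Summary statistics with a normal-approximation confidence interval
#'
#' Sample mean, sample standard deviation (n-1 denominator) and the
#' two-sided normal confidence interval `mean +/- z * sd / sqrt(n)`
#' (z = 1.96 at 95%). Non-finite values (e.g. the infinite-PSNR sentinel for
#' identical images) are excluded from the statistics; their count is
#' reported in `n_excluded` and flagged with a message.
#'
#' @param values numeric vector (>= 2 finite values).
#' @param confidence confidence level in (0, 1).
#' @return a `"summary_stats"` list with `mean`, `std`, `ci_low`, `ci_high`,
#'   `n`, `n_excluded`.
#' @examples
#' summarize(c(1, 2, 3))  # CI approximately [0.868, 3.132]
#' @export
summarize <- function(values, confidence = 0.95) {
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop("confidence must lie in (0, 1)", call. = FALSE)
  }
  fin <- values[is.finite(values)]
  n_excluded <- length(values) - length(fin)
  if (n_excluded > 0) {
    message(n_excluded, " non-finite value(s) excluded from summary")
  }
  n <- length(fin)
  if (n < 2L) stop("need at least 2 finite values for std/CI", call. = FALSE)
  m <- mean(fin)
  s <- sd(fin)
  z <- qnorm((1 + confidence) / 2)
  hw <- z * s / sqrt(n)
  structure(list(mean = m, std = s, ci_low = m - hw, ci_high = m + hw,
                 n = n, n_excluded = n_excluded),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("mean %.4f  std %.4f  %s CI [%.4f, %.4f]  (n = %d)\n",
              x$mean, x$std, "95%", x$ci_low, x$ci_high, x$n))
  invisible(x)
}
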
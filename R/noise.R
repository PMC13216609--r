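#' Derive a per-item random seed from a master seed
#'
#' Corruption and phantom generation use one master seed per experiment;
#' per-image seeds are derived from a counter so that results do not depend
#' on iteration order. The scheme is a fixed affine congruential map modulo
#' the Mersenne prime 2^31 - 1.
#'
#' @param master integer master seed.
#' @param index nonnegative integer counter (e.g. image index).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% m) * 48271 + as.numeric(index) * 104729 + 1
  as.integer(s %% (m - 1) + 1)
}

#' Noise specification
#'
#' Bundles a corruption kind, a severity level and a seed. For `gaussian`
#' and `speckle` the level is a variance on the \[0, 1\] intensity scale;
#' for `rician` the level is a variance v and the per-channel Gaussian
#' standard deviation is sigma = sqrt(v); for `poisson` the level is the
#' photon peak count (larger = less noise).
#'
#' @param kind one of `"gaussian"`, `"speckle"`, `"rician"`, `"poisson"`.
#' @param level positive severity parameter.
#' @param seed integer seed.
#' @export
noise_spec <- function(kind = c("gaussian", "speckle", "rician", "poisson"),
                       level, seed = 0L) {
  kind <- match.arg(kind)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) || level <= 0) {
    stop("noise level must be a positive finite number", call. = FALSE)
  }
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Corrupt an image according to a noise specification
#'
#' @param img grayscale image matrix in \[0, 1\].
#' @param spec a [noise_spec()].
#' @return corrupted image in \[0, 1\].
#' @export
corrupt <- function(img, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  switch(spec$kind,
    gaussian = add_gaussian(img, spec$level, spec$seed),
    speckle  = add_speckle(img, spec$level, spec$seed),
    rician   = add_rician(img, sqrt(spec$level), spec$seed),
    poisson  = add_poisson(img, spec$level, spec$seed)
  )
}

#' Additive white Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with the given variance on the
#' normalized intensity scale and clips the result to \[0, 1\] (the clipping
#' convention of MATLAB's `imnoise`).
#'
#' @param img grayscale image matrix in \[0, 1\].
#' @param variance noise variance (>= 0).
#' @param seed integer seed; the same (image, variance, seed) always yields
#'   a bit-identical result.
#' @return corrupted image.
#' @examples
#' img <- matrix(0.5, 32, 32)
#' noisy <- add_gaussian(img, 0.003, seed = 1)
#' @export
add_gaussian <- function(img, variance, seed = 0L) {
  img <- as_gray(img)
  if (!is.numeric(variance) || variance < 0) {
    stop("variance must be nonnegative", call. = FALSE)
  }
  if (variance == 0) return(img)
  e <- withr::with_seed(as.integer(seed),
                        matrix(rnorm(length(img), 0, sqrt(variance)), nrow(img)))
  clip01(img + e)
}

#' Multiplicative speckle noise
#'
#' Output is `I + n * I` where `n` is zero-mean with the requested variance.
#' The default multiplier is uniform on \[-sqrt(3 v), +sqrt(3 v)\], the
#' convention of MATLAB `imnoise(..., 'speckle')`; `multiplier = "gaussian"`
#' switches to a Gaussian multiplier for sensitivity checks.
#'
#' @inheritParams add_gaussian
#' @param multiplier distribution of the multiplicative factor.
#' @export
add_speckle <- function(img, variance, seed = 0L,
                        multiplier = c("uniform", "gaussian")) {
  img <- as_gray(img)
  multiplier <- match.arg(multiplier)
  if (!is.numeric(variance) || variance < 0) {
    stop("variance must be nonnegative", call. = FALSE)
  }
  if (variance == 0) return(img)
  n <- withr::with_seed(as.integer(seed), {
    if (multiplier == "uniform") {
      a <- sqrt(3 * variance)
      matrix(runif(length(img), -a, a), nrow(img))
    } else {
      matrix(rnorm(length(img), 0, sqrt(variance)), nrow(img))
    }
  })
  clip01(img + n * img)
}

#' Rician noise (MRI magnitude model)
#'
#' Simulates the magnitude of a complex signal whose real and imaginary
#' channels carry independent Gaussian noise:
#' `I_R = sqrt((I + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`,
#' clipped to \[0, 1\]. At zero signal this reduces to Rayleigh noise.
#'
#' @inheritParams add_gaussian
#' @param sigma standard deviation of each Gaussian channel (>= 0).
#' @export
add_rician <- function(img, sigma, seed = 0L) {
  img <- as_gray(img)
  if (!is.numeric(sigma) || sigma < 0) {
    stop("sigma must be nonnegative", call. = FALSE)
  }
  if (sigma == 0) return(img)
  out <- withr::with_seed(as.integer(seed), {
    n1 <- matrix(rnorm(length(img), 0, sigma), nrow(img))
    n2 <- matrix(rnorm(length(img), 0, sigma), nrow(img))
    sqrt((img + n1)^2 + n2^2)
  })
  clip01(out)
}

#' Rician probability density function
#'
#' Density of the magnitude of a complex value with true amplitude `nu` and
#' i.i.d. Gaussian noise of standard deviation `sigma` on both channels:
#' `p(x) = x/sigma^2 * exp(-(x^2 + nu^2) / (2 sigma^2)) * I0(x nu / sigma^2)`
#' for `x >= 0` and 0 otherwise, where `I0` is the modified Bessel function
#' of the first kind and order zero. Evaluated on the log scale with the
#' exponentially scaled Bessel function so that large `x nu / sigma^2` does
#' not overflow. At `nu = 0` this is the Rayleigh density.
#'
#' @param x quantiles (any real; negative values have density 0).
#' @param nu true signal amplitude (>= 0).
#' @param sigma Gaussian channel standard deviation (> 0).
#' @return vector of densities.
#' @export
rician_pdf <- function(x, nu, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (!is.numeric(nu) || nu < 0) stop("nu must be nonnegative", call. = FALSE)
  out <- numeric(length(x))
  pos <- is.finite(x) & x > 0
  xp <- x[pos]
  z <- xp * nu / sigma^2
  # log I0(z) = log(besselI(z, 0, scaled)) + z
  logi0 <- log(besselI(z, 0, expon.scaled = TRUE)) + z
  logp <- log(xp) - 2 * log(sigma) - (xp^2 + nu^2) / (2 * sigma^2) + logi0
  out[pos] <- exp(logp)
  out
}

#' Poisson (photon-counting) noise
#'
#' Scaled photon-count model: the image is interpreted as an expected photon
#' count per pixel after multiplication by `peak`, a Poisson draw is taken,
#' and the result is rescaled by `1/peak` and clipped. Larger `peak` means
#' less noise; the output is unbiased (pre-clipping) with variance
#' approximately `I / peak`.
#'
#' @inheritParams add_gaussian
#' @param peak positive photon peak count.
#' @export
add_poisson <- function(img, peak, seed = 0L) {
  img <- as_gray(img)
  if (!is.numeric(peak) || length(peak) != 1L || !is.finite(peak) || peak <= 0) {
    stop("peak must be positive", call. = FALSE)
  }
  out <- withr::with_seed(as.integer(seed),
                          matrix(rpois(length(img), img * peak) / peak, nrow(img)))
  clip01(out)
}

#' Default peak mapping for Poisson severity levels
#'
#' Maps qualitative severities to photon peak counts; used by the X-ray
#' corruption experiments.
#'
#' @param level one of `"low"`, `"mid"`, `"high"`.
#' @return photon peak count.
#' @export
poisson_peak <- function(level = c("low", "mid", "high")) {
  level <- match.arg(level)
  c(low = 1000, mid = 100, high = 25)[[level]]
}
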
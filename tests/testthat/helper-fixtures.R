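# shared fixtures: deterministic random images and small phantom corpora

rand_img <- function(h, w, seed = 1) {
  withr::with_seed(seed, matrix(runif(h * w), h, w))
}

# independent brute-force SSIM oracle: explicit loop over every valid
# window position with Gaussian weights
ssim_oracle <- function(a, b, window = 11L, sigma = 1.5, K1 = 0.01,
                        K2 = 0.03, L = 1) {
  r <- (window - 1) / 2
  k1d <- exp(-((-r:r)^2) / (2 * sigma^2))
  k1d <- k1d / sum(k1d)
  w <- outer(k1d, k1d)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  n <- nrow(a) - window + 1L
  m <- ncol(a) - window + 1L
  vals <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      wa <- a[i:(i + window - 1L), j:(j + window - 1L)]
      wb <- b[i:(i + window - 1L), j:(j + window - 1L)]
      mu1 <- sum(w * wa); mu2 <- sum(w * wb)
      s11 <- sum(w * wa * wa) - mu1^2
      s22 <- sum(w * wb * wb) - mu2^2
      s12 <- sum(w * wa * wb) - mu1 * mu2
      vals[i, j] <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
        ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
    }
  }
  mean(vals)
}

# chi-square goodness of fit of the Rician sampler against rician_pdf,
# binned at theoretical quantiles (the open-ended last bin absorbs the
# probability mass relocated to 1 by intensity clipping)
rician_gof_p <- function(nu, sigma, n = 1e5, seed = 1, n_bins = 25L) {
  img <- matrix(nu, 250, n / 250)
  x <- as.numeric(add_rician(img, sigma, seed = seed))
  hi <- nu + 8 * sigma
  grid <- seq(0, hi, length.out = 4001)
  dens <- rician_pdf(grid, nu, sigma)
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  cdf <- c(0, cdf / max(cdf))
  probs <- seq(0, 1, length.out = n_bins + 1L)
  edges <- stats::approx(cdf, grid, xout = probs[-c(1, n_bins + 1L)],
                         ties = "ordered")$y
  counts <- tabulate(findInterval(x, edges) + 1L, nbins = n_bins)
  stats::chisq.test(counts, p = rep(1 / n_bins, n_bins))$p.value
}
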
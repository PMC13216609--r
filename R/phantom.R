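# Deterministic synthetic phantoms: piecewise-smooth anatomy-like scenes with
# curved boundaries, graded contrast and optional band-limited texture. They
# stand in for ultrasound / MRI / X-ray test images so the whole pipeline is
# exercisable without downloads.

.smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# anti-aliased membership of an implicit region: d is a signed "distance"
# (<= 1 inside for ellipse-style shapes), aa the transition width
.aa_inside <- function(d, aa) .smoothstep((1 - d) / aa + 0.5)

.smooth_noise <- function(h, w, sigma = 2) {
  z <- matrix(rnorm(h * w), h, w)
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  # separable filtering with replicate padding
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
  zp <- z[pad_idx(h), pad_idx(w)]
  tmp <- matrix(0, h, w + 2L * r)
  for (j in seq_along(k)) tmp <- tmp + k[j] * zp[j:(j + h - 1L), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * tmp[, j:(j + w - 1L), drop = FALSE]
  out / sd(out)
}

#' Generate a synthetic grayscale phantom
#'
#' Builds a deterministic piecewise-smooth test image: a dim, slowly varying
#' background plus `n_structures` anti-aliased curved structures (ellipses,
#' annuli and wedges) whose mean intensities are spread over at least half of
#' the dynamic range, optionally overlaid with band-limited texture inside
#' the structures. Three presets mimic coarse characteristics of the target
#' modalities: `us_like` places structures inside a bright fan-shaped sector,
#' `mri_like` nests them inside a head-like ellipse with a bright rim, and
#' `xray_like` uses elongated high-contrast structures on a dark background.
#'
#' @param kind one of `"us_like"`, `"mri_like"`, `"xray_like"`.
#' @param height,width image dimensions (>= 128).
#' @param n_structures number of foreground structures (>= 1).
#' @param texture_amplitude standard deviation of the within-structure
#'   texture, in intensity units (0 to 0.2).
#' @param seed integer seed; equal specs give bit-identical phantoms.
#' @return grayscale image matrix in \[0, 1\].
#' @examples
#' ph <- make_phantom("us_like", 128, 128, seed = 7)
#' @export
make_phantom <- function(kind = c("us_like", "mri_like", "xray_like"),
                         height = 256L, width = 256L, n_structures = 5L,
                         texture_amplitude = 0.05, seed = 0L) {
  kind <- match.arg(kind)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 128L || width < 128L) stop("phantom size must be >= 128", call. = FALSE)
  n_structures <- as.integer(n_structures)
  if (n_structures < 1L) stop("n_structures must be >= 1", call. = FALSE)
  if (texture_amplitude < 0 || texture_amplitude > 0.2) {
    stop("texture_amplitude must lie in [0, 0.2]", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    yg <- matrix(seq(0, 1, length.out = height), height, width)
    xg <- matrix(seq(0, 1, length.out = width), height, width, byrow = TRUE)
    aa_x <- 1.5 / min(height, width)  # ~1.5 px anti-aliasing band

    ang <- runif(1, 0, 2 * pi)
    img <- 0.06 + 0.05 * (cos(ang) * xg + sin(ang) * yg) + 0.02 * xg * yg
    support <- matrix(1, height, width)

    if (kind == "us_like") {
      # fan-shaped insonified sector opening downwards from the top centre
      cx <- 0.5; cy <- -0.05
      theta <- atan2(xg - cx, yg - cy)
      rr <- sqrt((xg - cx)^2 + (yg - cy)^2)
      half <- runif(1, 0.55, 0.75)
      support <- .smoothstep((half - abs(theta)) / 0.03) *
        .smoothstep((1.15 - rr) / 0.03)
      img <- img + 0.22 * support
    } else if (kind == "mri_like") {
      a <- runif(1, 0.40, 0.46); b <- runif(1, 0.33, 0.4)
      d <- sqrt(((xg - 0.5) / a)^2 + ((yg - 0.5) / b)^2)
      head <- .aa_inside(d, aa_x / a)
      rim <- .aa_inside(d, aa_x / a) - .aa_inside(d / 0.92, aa_x / a)
      img <- img * (1 - head) + head * 0.35 + pmax(rim, 0) * 0.55
      support <- head
    }

    levels <- seq(0.30, 0.95, length.out = max(n_structures, 2L))[seq_len(n_structures)]
    levels <- sample(levels)
    shapes <- rep(c("ellipse", "annulus", "wedge"), length.out = n_structures)
    for (i in seq_len(n_structures)) {
      cx <- runif(1, 0.25, 0.75); cy <- runif(1, 0.25, 0.75)
      th <- runif(1, 0, pi)
      if (kind == "xray_like") {
        a <- runif(1, 0.05, 0.09); b <- runif(1, 0.18, 0.35)  # elongated
      } else {
        a <- runif(1, 0.07, 0.18); b <- runif(1, 0.07, 0.18)
      }
      dx <- xg - cx; dy <- yg - cy
      u <- (cos(th) * dx + sin(th) * dy) / a
      v <- (-sin(th) * dx + cos(th) * dy) / b
      d <- sqrt(u^2 + v^2)
      alpha <- switch(shapes[i],
        ellipse = .aa_inside(d, aa_x / min(a, b)),
        annulus = pmax(.aa_inside(d, aa_x / min(a, b)) -
                       .aa_inside(d / 0.62, aa_x / min(a, b)), 0),
        wedge = .aa_inside(d, aa_x / min(a, b)) *
          .smoothstep((atan2(v, u) + 0.5) / 0.08)
      )
      alpha <- alpha * pmax(support, if (kind == "xray_like") 1 else 0.15)
      img <- img * (1 - alpha) + alpha * levels[i]
    }

    if (texture_amplitude > 0) {
      tex <- .smooth_noise(height, width, sigma = 1.6)
      img <- img + texture_amplitude * tex * pmax(support, 0.25)
    }
    clip01(img)
  })
}

#' Generate a corpus of phantoms
#'
#' Produces `n` phantoms with per-image seeds derived from the master seed by
#' [derive_seed()], so the corpus is reproducible and independent of
#' generation order. Structure counts are varied per image for diversity.
#'
#' @inheritParams make_phantom
#' @param n number of phantoms (>= 1).
#' @param seed master seed.
#' @return named list of image matrices; names are stable zero-padded ids.
#' @export
make_dataset <- function(n, kind = c("us_like", "mri_like", "xray_like"),
                         height = 256L, width = 256L,
                         texture_amplitude = 0.05, seed = 0L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  ids <- sprintf("%s_%05d", kind, seq_len(n))
  imgs <- lapply(seq_len(n), function(i) {
    si <- derive_seed(seed, i)
    make_phantom(kind, height, width,
                 n_structures = 4L + (si %% 5L),
                 texture_amplitude = texture_amplitude, seed = si)
  })
  names(imgs) <- ids
  imgs
}
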
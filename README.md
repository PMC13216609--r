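# hwdenoise

Hybrid wavelet–autoencoder denoising for grayscale medical images
(ultrasound, MRI, X-ray), with the noise simulators, synthetic phantoms,
quality metrics and evaluation harness needed to exercise the whole
pipeline without any external data.

## Who this is for

Researchers and engineers who need a reproducible, fully scriptable
implementation of a hybrid denoiser that combines classical multi-wavelet
shrinkage with patch-based convolutional networks — either to denoise their
own PNG/TIFF images, to benchmark against the Wiener baseline, or to study
the method itself under controlled synthetic corruption.

## The method

Given a noisy image `I_n`, three stages produce the restored image:

1. **Hybrid wavelet branch.** Five wavelet families (sym4, db4, bior3.3,
   coif2, haar) each denoise the full image by 4-level DWT, soft
   thresholding of detail sub-bands, and reconstruction. Candidates are
   scored by PSNR and the best two are fused pixel-wise with
   PSNR-proportional weights

   α_k = 10^(PSNR_k/10) / Σ_j 10^(PSNR_j/10),  W_fused = Σ_k α_k W_k.

2. **Autoencoder branch.** Non-overlapping 64×64 patches pass through a
   six-layer convolutional autoencoder (3×3 kernels, stride 1, same
   padding, channels 1–64–32–16–32–64–1, ReLU, linear output; 47,441
   parameters) trained with Adam on the MSE loss
   L(x, x̂) = (1/n) Σ (x_i − x̂_i)².

3. **Fusion CNN.** Each patch pair (autoencoder output, hybrid wavelet
   patch) is stacked into a 2-channel input to a second network with the
   same layer chain (48,017 parameters), trained against clean patches; its
   outputs reassemble into the final image.

Noise simulators cover the four families used in the evaluation protocol —
additive Gaussian, multiplicative speckle (both at variances
0.003/0.03/0.1), Rician (`I_R = sqrt((I+n1)² + n2²)`) and Poisson photon
counting — all with MATLAB `imnoise`-style \[0,1\] clipping semantics and
counter-derived per-image seeds.

## Worked example

```r
library(hwdenoise)

ph    <- make_phantom("us_like", 256, 256, seed = 7)   # clean ground truth
noisy <- add_speckle(ph, 0.01, seed = 8)               # multiplicative noise
cat("noisy:   PSNR", round(psnr(ph, noisy), 2), "dB  SSIM", round(ssim(ph, noisy), 3), "\n")

h <- hybrid_wavelet_denoise(ph, noisy)                 # wavelet branch alone
cat("fused:   PSNR", round(psnr(ph, h$image), 2), "dB  SSIM", round(ssim(ph, h$image), 3), "\n")
cat("selected:", h$weights$families, " alphas:", round(h$weights$alphas, 4), "\n")

summarize(c(1, 2, 3))                                  # CI arithmetic
```

This prints:

```
noisy:   PSNR 29.89 dB  SSIM 0.801
fused:   PSNR 33.4 dB  SSIM 0.905
selected: bior3.3 coif2  alphas: 0.6347 0.3653
mean 2.0000  std 1.0000  95% CI [0.8684, 3.1316]  (n = 3)
```

The speckled phantom sits at 29.9 dB; shrinkage with the two
best-performing families (here bior3.3 and coif2, weighted ≈ 0.63/0.37 by
their linear-scale SNR) lifts it to 33.4 dB and repairs most of the
structural similarity. The full learned pipeline is driven the same way:

```r
imgs <- make_dataset(16, "us_like", 128, 128, seed = 2)
res <- ablation_run(imgs, noise_spec("speckle", 0.003, seed = 102),
                    ae_cfg     = hw_train_config(epochs = 30, batch_size = 4, seed = 202),
                    fusion_cfg = hw_train_config(epochs = 30, batch_size = 4, seed = 302))
res$summary[, c("method", "psnr_mean", "ssim_mean")]
```

which trains both networks on the 80% training split and evaluates every
method variant on the held-out images — on this corpus the noisy baseline
of 35.3 dB / 0.935 SSIM rises to 38.8 dB / 0.982 for the full pipeline,
with the ablation variants (wavelet only 36.2, autoencoder only 38.9,
unweighted average 38.6) in between.

## Command line

A thin CLI over the same functions lives at `inst/cli/hwdenoise.R`:

```sh
Rscript inst/cli/hwdenoise.R phantom --kind us_like --n 64 --size 256 --seed 7 --out data/
Rscript inst/cli/hwdenoise.R corrupt --kind speckle --level 0.003 --seed 1 --in data/ --out noisy/
Rscript inst/cli/hwdenoise.R run --out experiment/ --seed 1
```

`run` executes the full staged experiment (corrupt → split → train →
denoise → evaluate) and writes manifests, checkpoints, per-image metrics,
summary tables and the resolved YAML configuration under the output
directory; re-running resumes from existing checkpoints.

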
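#' Wavelet-branch options
#'
#' Collects the tunables of the hybrid wavelet branch: candidate families,
#' decomposition depth, how many candidates to fuse and how to rank them.
#'
#' @param families candidate wavelet families.
#' @param levels decomposition depth.
#' @param k_select number of candidates fused (default 2, the best pair).
#' @param selection ranking criterion, `"psnr"` or `"psnr_ssim"`.
#' @param threshold_rule shrinkage rule, `"universal"` or `"bayes"`.
#' @export
hw_wavelet_opts <- function(families = wavelet_families(), levels = 4L,
                            k_select = 2L,
                            selection = c("psnr", "psnr_ssim"),
                            threshold_rule = c("universal", "bayes")) {
  list(families = families, levels = as.integer(levels),
       k_select = as.integer(k_select), selection = match.arg(selection),
       threshold_rule = match.arg(threshold_rule))
}

.hybrid_wrap <- function(reference, noisy, opts) {
  hybrid_wavelet_denoise(reference, noisy, k_select = opts$k_select,
                         selection = opts$selection, families = opts$families,
                         levels = opts$levels,
                         threshold_rule = opts$threshold_rule)
}

#' Train the full hybrid denoiser on a corpus of clean images
#'
#' Executes the staged protocol: every image is corrupted with a seed derived
#' from the noise seed and its index; the corpus is split 80/20 at the image
#' level; the autoencoder is trained on (noisy patch, clean patch) pairs from
#' the training images; it is then frozen and the fusion network is trained
#' on two-channel stacks of (autoencoder output patch, hybrid wavelet patch)
#' against the clean patches. Patch extraction happens strictly after the
#' split, so no image contributes patches to both sides.
#'
#' @param images named list of clean grayscale images.
#' @param noise a [noise_spec()]; its seed acts as the corruption master seed.
#' @param split_fraction training fraction at image level.
#' @param wavelet a [hw_wavelet_opts()].
#' @param ae_cfg,fusion_cfg [hw_train_config()]s for the two networks.
#' @param patch_size patch side length.
#' @param verbose print stage progress.
#' @return a `"hw_denoiser"` bundling both trained models, the split, the
#'   corrupted images and all options.
#' @export
train_denoiser <- function(images, noise, split_fraction = 0.8,
                           wavelet = hw_wavelet_opts(),
                           ae_cfg = hw_train_config(),
                           fusion_cfg = hw_train_config(),
                           patch_size = 64L, verbose = FALSE) {
  stopifnot(inherits(noise, "noise_spec"))
  if (is.null(names(images))) {
    names(images) <- sprintf("img_%05d", seq_along(images))
  }
  ids <- names(images)
  noisy <- lapply(seq_along(images), function(i) {
    sp <- noise_spec(noise$kind, noise$level, derive_seed(noise$seed, i))
    corrupt(images[[i]], sp)
  })
  names(noisy) <- ids
  split <- split_dataset(ids, split_fraction, seed = noise$seed)

  say <- function(...) if (verbose) message(...)
  say("training autoencoder on ", length(split$train_ids), " images")
  ae_in <- list(); ae_tg <- list(); parents <- character(0)
  for (id in split$train_ids) {
    pn <- extract_patches(noisy[[id]], patch_size)
    pc <- extract_patches(images[[id]], patch_size)
    ae_in <- c(ae_in, pn$patches)
    ae_tg <- c(ae_tg, pc$patches)
    parents <- c(parents, rep(id, length(pn$patches)))
  }
  assert_no_leakage(parents, split)
  ae <- init_model(build_autoencoder(), seed = ae_cfg$seed)
  ae <- train(ae, ae_in, ae_tg, ae_cfg)

  say("training fusion network")
  fu_in <- list(); fu_tg <- list()
  for (id in split$train_ids) {
    pn <- extract_patches(noisy[[id]], patch_size)
    pc <- extract_patches(images[[id]], patch_size)
    ae_out <- denoise_patches(ae, pn$patches)
    wav <- .hybrid_wrap(images[[id]], noisy[[id]], wavelet)$image
    pw <- extract_patches(wav, patch_size)$patches
    two <- lapply(seq_along(ae_out), function(k) {
      a <- array(0, c(dim(ae_out[[k]]), 2L))
      a[, , 1] <- ae_out[[k]]  # channel 1: autoencoder output
      a[, , 2] <- pw[[k]]      # channel 2: hybrid wavelet patch
      a
    })
    fu_in <- c(fu_in, two)
    fu_tg <- c(fu_tg, pc$patches)
  }
  fusion <- init_model(build_fusion(), seed = fusion_cfg$seed)
  fusion <- train(fusion, fu_in, fu_tg, fusion_cfg)

  structure(list(ae = ae, fusion = fusion, wavelet = wavelet,
                 patch_size = patch_size, split = split, noise = noise,
                 noisy_images = noisy),
            class = "hw_denoiser")
}

#' Denoise a full image with the trained hybrid pipeline
#'
#' Runs the autoencoder branch patch-wise, the hybrid wavelet branch on the
#' full image, stacks both per patch into the two-channel fusion network and
#' reassembles the fused patches. With `reference = NULL` (blind mode, no
#' clean image available) the wavelet candidates are scored against the
#' autoencoder output as a pseudo-reference.
#'
#' @param noisy corrupted grayscale image.
#' @param denoiser a trained `"hw_denoiser"` (or a list with elements `ae`,
#'   `fusion`, `wavelet`, `patch_size`).
#' @param reference optional clean image for candidate scoring.
#' @return list with the final `image`, the branch images `ae_image` and
#'   `wavelet_image`, and the wavelet fusion `weights`.
#' @export
denoise_image <- function(noisy, denoiser, reference = NULL) {
  noisy <- as_gray(noisy)
  ps <- denoiser$patch_size
  pe <- extract_patches(noisy, ps)
  ae_patches <- denoise_patches(denoiser$ae, pe$patches)
  ae_img <- clip01(reassemble(ae_patches, pe$grid))
  ref <- if (is.null(reference)) ae_img else as_gray(reference)
  hw <- .hybrid_wrap(ref, noisy, denoiser$wavelet)
  wav_img <- hw$image
  pw <- extract_patches(wav_img, ps)$patches
  pa <- extract_patches(ae_img, ps)$patches
  two <- lapply(seq_along(pa), function(k) {
    a <- array(0, c(dim(pa[[k]]), 2L))
    a[, , 1] <- pa[[k]]
    a[, , 2] <- pw[[k]]
    a
  })
  fused <- denoise_patches(denoiser$fusion, two)
  out <- clip01(reassemble(fused, pe$grid))
  list(image = out, ae_image = ae_img, wavelet_image = wav_img,
       weights = hw$weights)
}

#' Evaluate all comparison methods on one image
#'
#' Scores the six methods of the evaluation protocol — the noisy input, the
#' adaptive Wiener baseline, the hybrid wavelet branch alone, the
#' autoencoder alone, their unweighted average, and the full proposed
#' pipeline — against the clean reference with PSNR and SSIM. All methods
#' see the identical noisy realization.
#'
#' @param clean clean reference image.
#' @param noisy corrupted image.
#' @param denoiser trained `"hw_denoiser"`.
#' @param wiener_window window for [wiener_baseline()].
#' @param image_id identifier recorded in the result.
#' @return data.frame with columns `image_id`, `method`, `psnr_db`, `ssim`.
#' @export
evaluate_methods <- function(clean, noisy, denoiser, wiener_window = c(3L, 3L),
                             image_id = NA_character_) {
  clean <- as_gray(clean)
  res <- denoise_image(noisy, denoiser, reference = clean)
  imgs <- list(
    noisy = noisy,
    wiener = wiener_baseline(noisy, wiener_window),
    wavelet_only = res$wavelet_image,
    ae_only = res$ae_image,
    avg_fusion = clip01((res$wavelet_image + res$ae_image) / 2),
    proposed = res$image
  )
  data.frame(
    image_id = image_id,
    method = names(imgs),
    psnr_db = vapply(imgs, function(im) psnr(clean, im), numeric(1)),
    ssim = vapply(imgs, function(im) ssim(clean, im), numeric(1)),
    row.names = NULL
  )
}

#' Ablation / evaluation harness
#'
#' Trains the pipeline on a corpus under one noise condition and evaluates
#' every method variant on the held-out test images, summarising PSNR and
#' SSIM per method with mean, standard deviation and 95% confidence
#' interval. The method set reproduces the ablation design: wavelet branch
#' only, autoencoder only, their unweighted average fusion, and the full
#' proposed pipeline, alongside the noisy input and the Wiener baseline.
#'
#' @inheritParams train_denoiser
#' @param wiener_window window for the Wiener baseline.
#' @return list with `records` (per image and method) and `summary` (one row
#'   per method).
#' @export
ablation_run <- function(images, noise, split_fraction = 0.8,
                         wavelet = hw_wavelet_opts(),
                         ae_cfg = hw_train_config(),
                         fusion_cfg = hw_train_config(),
                         patch_size = 64L, wiener_window = c(3L, 3L),
                         verbose = FALSE) {
  den <- train_denoiser(images, noise, split_fraction, wavelet,
                        ae_cfg, fusion_cfg, patch_size, verbose)
  records <- do.call(rbind, lapply(den$split$test_ids, function(id) {
    evaluate_methods(images[[id]], den$noisy_images[[id]], den,
                     wiener_window, image_id = id)
  }))
  list(records = records, summary = summarize_records(records),
       denoiser = den)
}

#' Summarise per-image records into a per-method table
#'
#' @param records data.frame as returned by [evaluate_methods()].
#' @return data.frame with one row per method: mean/std/CI for PSNR and SSIM.
#' @export
summarize_records <- function(records) {
  methods <- unique(records$method)
  do.call(rbind, lapply(methods, function(m) {
    r <- records[records$method == m, ]
    sp <- suppressMessages(summarize(r$psnr_db))
    ss <- suppressMessages(summarize(r$ssim))
    data.frame(method = m, n = sp$n,
               psnr_mean = sp$mean, psnr_std = sp$std,
               psnr_ci_low = sp$ci_low, psnr_ci_high = sp$ci_high,
               ssim_mean = ss$mean, ssim_std = ss$std,
               ssim_ci_low = ss$ci_low, ssim_ci_high = ss$ci_high,
               row.names = NULL)
  }))
}

# experiment orchestration ----------------------------------------------------

#' Default experiment configuration
#'
#' Returns the declarative configuration consumed by [run_experiment()];
#' any element can be overridden via `...` (nested lists are replaced
#' wholesale). A YAML file with the same structure can be loaded with
#' [load_experiment_config()].
#'
#' @param ... named overrides.
#' @export
default_experiment_config <- function(...) {
  cfg <- list(
    phantom = list(kind = "us_like", n = 16L, height = 128L, width = 128L,
                   texture_amplitude = 0.05),
    dataset_path = NULL,
    noise = list(kind = "speckle", level = 0.003),
    split_fraction = 0.8,
    wavelet = list(levels = 4L, k_select = 2L, selection = "psnr",
                   threshold_rule = "universal"),
    train = list(learning_rate = 1e-3, epochs = 10L, batch_size = 128L),
    patch_size = 64L,
    wiener_window = c(3L, 3L),
    seed = 0L,
    output_dir = NULL,
    force = FALSE
  )
  utils::modifyList(cfg, list(...))
}

#' @rdname default_experiment_config
#' @param path YAML configuration file.
#' @export
load_experiment_config <- function(path) {
  do.call(default_experiment_config, yaml::read_yaml(path))
}

.load_input_images <- function(cfg) {
  if (!is.null(cfg$dataset_path)) {
    files <- sort(list.files(cfg$dataset_path, "\\.(png|tif|tiff)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(files) < 2L) stop("dataset_path must contain >= 2 images", call. = FALSE)
    imgs <- lapply(files, read_gray)
    names(imgs) <- tools::file_path_sans_ext(basename(files))
    imgs
  } else {
    p <- cfg$phantom
    make_dataset(p$n, p$kind, p$height, p$width,
                 texture_amplitude = p$texture_amplitude, seed = cfg$seed)
  }
}

#' Run a full experiment from a declarative configuration
#'
#' Stages: load or generate the clean corpus, corrupt it, split at image
#' level, train the autoencoder and fusion networks (reusing checkpoints in
#' `output_dir` unless `force`), evaluate all method variants on the test
#' images, and persist manifests, per-image metrics, summary tables and the
#' resolved configuration. Re-running with an identical configuration
#' reproduces identical summaries.
#'
#' @param cfg configuration list from [default_experiment_config()] /
#'   [load_experiment_config()], or a path to a YAML file.
#' @param verbose print stage progress.
#' @return invisibly, the list returned by [ablation_run()].
#' @export
run_experiment <- function(cfg = default_experiment_config(), verbose = FALSE) {
  if (is.character(cfg)) cfg <- load_experiment_config(cfg)
  out_dir <- cfg$output_dir
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  images <- .load_input_images(cfg)
  noise <- noise_spec(cfg$noise$kind, cfg$noise$level, seed = cfg$seed)
  wavelet <- hw_wavelet_opts(levels = cfg$wavelet$levels,
                             k_select = cfg$wavelet$k_select,
                             selection = cfg$wavelet$selection,
                             threshold_rule = cfg$wavelet$threshold_rule)
  tr <- cfg$train
  ae_cfg <- hw_train_config(tr$learning_rate, tr$epochs, tr$batch_size,
                            seed = derive_seed(cfg$seed, 101L))
  fu_cfg <- hw_train_config(tr$learning_rate, tr$epochs, tr$batch_size,
                            seed = derive_seed(cfg$seed, 202L))

  ae_ckpt <- if (persist) file.path(out_dir, "ae.rds") else ""
  fu_ckpt <- if (persist) file.path(out_dir, "fusion.rds") else ""
  reuse_ae <- persist && !isTRUE(cfg$force) && file.exists(ae_ckpt)
  reuse_fu <- persist && !isTRUE(cfg$force) && file.exists(fu_ckpt)

  ids <- names(images)
  noisy <- lapply(seq_along(images), function(i) {
    corrupt(images[[i]], noise_spec(noise$kind, noise$level,
                                    derive_seed(noise$seed, i)))
  })
  names(noisy) <- ids
  split <- split_dataset(ids, cfg$split_fraction, seed = cfg$seed)

  if (reuse_ae && reuse_fu) {
    den <- structure(list(ae = load_checkpoint(ae_ckpt),
                          fusion = load_checkpoint(fu_ckpt),
                          wavelet = wavelet, patch_size = cfg$patch_size,
                          split = split, noise = noise, noisy_images = noisy),
                     class = "hw_denoiser")
  } else if (reuse_ae) {
    # stage isolation: retrain only the fusion network on the frozen AE
    ae <- load_checkpoint(ae_ckpt)
    den <- .train_fusion_stage(images, noisy, split, ae, wavelet, fu_cfg,
                               cfg$patch_size, noise)
  } else {
    den <- train_denoiser(images, noise, cfg$split_fraction, wavelet,
                          ae_cfg, fu_cfg, cfg$patch_size, verbose)
    split <- den$split
  }
  if (persist) {
    if (!reuse_ae) save_checkpoint(den$ae, ae_ckpt)
    if (!reuse_fu || !reuse_ae) save_checkpoint(den$fusion, fu_ckpt)
  }

  records <- do.call(rbind, lapply(split$test_ids, function(id) {
    evaluate_methods(images[[id]], den$noisy_images[[id]], den,
                     cfg$wiener_window, image_id = id)
  }))
  summary <- summarize_records(records)

  if (persist) {
    write.csv(data.frame(image_id = ids, kind = noise$kind,
                         level = noise$level,
                         seed = vapply(seq_along(ids), function(i)
                           derive_seed(noise$seed, i), integer(1))),
              file.path(out_dir, "manifest_corrupt.csv"), row.names = FALSE)
    write.csv(data.frame(image_id = c(split$train_ids, split$test_ids),
                         role = rep(c("train", "test"),
                                    c(length(split$train_ids),
                                      length(split$test_ids)))),
              file.path(out_dir, "manifest_split.csv"), row.names = FALSE)
    write.csv(records, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    prov <- cfg
    prov$package_version <- as.character(utils::packageVersion("hwdenoise"))
    yaml::write_yaml(prov, file.path(out_dir, "config.yaml"))
  }
  invisible(list(records = records, summary = summary, denoiser = den))
}

.train_fusion_stage <- function(images, noisy, split, ae, wavelet, fu_cfg,
                                patch_size, noise) {
  fu_in <- list(); fu_tg <- list()
  for (id in split$train_ids) {
    pn <- extract_patches(noisy[[id]], patch_size)
    pc <- extract_patches(images[[id]], patch_size)
    ae_out <- denoise_patches(ae, pn$patches)
    wav <- .hybrid_wrap(images[[id]], noisy[[id]], wavelet)$image
    pw <- extract_patches(wav, patch_size)$patches
    two <- lapply(seq_along(ae_out), function(k) {
      a <- array(0, c(dim(ae_out[[k]]), 2L))
      a[, , 1] <- ae_out[[k]]
      a[, , 2] <- pw[[k]]
      a
    })
    fu_in <- c(fu_in, two)
    fu_tg <- c(fu_tg, pc$patches)
  }
  fusion <- init_model(build_fusion(), seed = fu_cfg$seed)
  fusion <- train(fusion, fu_in, fu_tg, fu_cfg)
  structure(list(ae = ae, fusion = fusion, wavelet = wavelet,
                 patch_size = patch_size, split = split, noise = noise,
                 noisy_images = noisy),
            class = "hw_denoiser")
}
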
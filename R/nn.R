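# Patch-based convolutional networks: a denoising autoencoder (single-channel
# input) and a two-channel fusion network, both six stride-1 same-padded 3x3
# convolutions with the filter chain 64-32-16-32-64-1, ReLU activations and a
# linear single-channel output. There is no spatial down/upsampling: the
# "encoder/decoder" narrows and widens the channel dimension only.

.hw_filter_chain <- c(64L, 32L, 16L, 32L, 64L, 1L)

.net_spec <- function(name, in_channels) {
  filters <- .hw_filter_chain
  chain <- c(in_channels, filters)
  param_count <- sum(9L * chain[-length(chain)] * filters + filters)
  structure(list(name = name, in_channels = in_channels, filters = filters,
                 kernel = c(3L, 3L), stride = 1L, padding = "same",
                 activations = c(rep("relu", length(filters) - 1L), "linear"),
                 param_count = param_count),
            class = "net_spec")
}

#' Network architectures
#'
#' `build_autoencoder()` returns the specification of the patch denoising
#' autoencoder (input 64x64x1); `build_fusion()` the two-channel fusion
#' network that stacks the autoencoder output and the hybrid wavelet patch
#' (input 64x64x2). Both consist of six 3x3 stride-1 same-padded
#' convolutions with 64-32-16-32-64-1 filters, ReLU on all but the linear
#' output layer. Parameter counts follow the closed form
#' `sum(3^2 * c_in * c_out + c_out)` over the layer chain: 47,441 for the
#' autoencoder and 48,017 for the fusion network.
#'
#' @return a `"net_spec"` object; the `param_count` field carries the total
#'   number of trainable parameters.
#' @examples
#' build_autoencoder()$param_count  # 47441
#' build_fusion()$param_count       # 48017
#' @export
build_autoencoder <- function() .net_spec("autoencoder", 1L)

#' @rdname build_autoencoder
#' @export
build_fusion <- function() .net_spec("fusion", 2L)

#' @export
print.net_spec <- function(x, ...) {
  cat(sprintf("%s: %d conv layers (3x3, stride 1, same), channels %s, %d parameters\n",
              x$name, length(x$filters),
              paste(c(x$in_channels, x$filters), collapse = "-"),
              x$param_count))
  invisible(x)
}

#' Training configuration
#'
#' Hyperparameters shared by both networks: Adam optimizer minimising the
#' mean squared error between output and clean target for a fixed number of
#' epochs. The learning rate defaults to Adam's conventional 1e-3.
#'
#' @param learning_rate positive Adam step size.
#' @param epochs number of passes over the training patches (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param seed integer seed controlling weight initialisation and shuffling.
#' @export
hw_train_config <- function(learning_rate = 1e-3, epochs = 10L,
                            batch_size = 128L, seed = 0L) {
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (is.na(batch_size) || batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("learning_rate must be positive", call. = FALSE)
  }
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size, loss = "mse",
                 seed = as.integer(seed)),
            class = "hw_train_config")
}

#' Initialise an untrained model
#'
#' Glorot-uniform weight initialisation (fan counts include the 3x3 kernel
#' support), zero biases, reproducible from the seed.
#'
#' @param spec a `"net_spec"` from [build_autoencoder()] or [build_fusion()].
#' @param seed integer seed.
#' @return a `"hw_model"` with weight matrices `W` (one `c_out x 9 c_in`
#'   matrix per layer), bias vectors `b` and the spec.
#' @export
init_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "net_spec"))
  chain <- c(spec$in_channels, spec$filters)
  withr::with_seed(as.integer(seed), {
    W <- vector("list", length(spec$filters))
    b <- vector("list", length(spec$filters))
    for (l in seq_along(spec$filters)) {
      cin <- chain[l]; cout <- chain[l + 1L]
      fan_in <- 9 * cin; fan_out <- 9 * cout
      lim <- sqrt(6 / (fan_in + fan_out))
      W[[l]] <- matrix(runif(cout * 9 * cin, -lim, lim), cout, 9 * cin)
      b[[l]] <- numeric(cout)
    }
    structure(list(spec = spec, W = W, b = b, loss_history = numeric(0)),
              class = "hw_model")
  })
}

# coerce a list of patches (h x w matrices, or h x w x c arrays) into the
# flat (h, w, c, n) array the C++ kernels expect
.stack_patches <- function(patches, channels) {
  n <- length(patches)
  d1 <- dim(patches[[1]])
  h <- d1[1]; w <- d1[2]
  arr <- array(0, c(h, w, channels, n))
  for (i in seq_len(n)) {
    p <- patches[[i]]
    dp <- dim(p)
    pc <- if (length(dp) == 3L) dp[3] else 1L
    if (dp[1] != h || dp[2] != w || pc != channels) {
      stop(sprintf("patch %d has shape %s; expected %dx%dx%d",
                   i, paste(dp, collapse = "x"), h, w, channels), call. = FALSE)
    }
    arr[, , , i] <- p
  }
  arr
}

#' Train a patch network
#'
#' Minimises the mean squared error between network output and clean target
#' patches with Adam. Training is deterministic for a fixed seed on a single
#' thread: the per-epoch loss trajectory is bit-reproducible.
#'
#' @param model an initialised or previously trained `"hw_model"`.
#' @param inputs list of input patches: `h x w` matrices for the
#'   autoencoder, `h x w x 2` arrays for the fusion network.
#' @param targets list of clean target patches (`h x w` matrices).
#' @param cfg a [hw_train_config()].
#' @return the trained `"hw_model"`; `$loss_history` holds the per-epoch
#'   mean training loss.
#' @export
train <- function(model, inputs, targets, cfg = hw_train_config()) {
  stopifnot(inherits(model, "hw_model"), inherits(cfg, "hw_train_config"))
  if (length(inputs) == 0L) stop("empty training set", call. = FALSE)
  if (length(inputs) != length(targets)) {
    stop("inputs and targets must have equal length", call. = FALSE)
  }
  cin <- model$spec$in_channels
  x <- .stack_patches(inputs, cin)
  y <- .stack_patches(targets, 1L)
  if (!identical(dim(x)[1:2], dim(y)[1:2])) {
    stop("input and target patches must share spatial dimensions", call. = FALSE)
  }
  d <- dim(x)
  fit <- cpp_cnn_train(model$W, model$b, as.numeric(x), as.numeric(y),
                       as.integer(d), cfg$epochs, cfg$batch_size,
                       cfg$learning_rate, cfg$seed)
  model$W <- fit$W
  model$b <- fit$b
  model$loss_history <- c(model$loss_history, fit$loss)
  model
}

#' Run a model over patches
#'
#' Deterministic inference pass; outputs are clipped to \[0, 1\] and returned
#' in input order.
#'
#' @param model a `"hw_model"`.
#' @param patches list of patches matching the model's input shape.
#' @param batch_size inference batch size.
#' @return list of denoised `h x w` patch matrices (empty for empty input).
#' @export
denoise_patches <- function(model, patches, batch_size = 64L) {
  stopifnot(inherits(model, "hw_model"))
  if (length(patches) == 0L) return(list())
  x <- .stack_patches(patches, model$spec$in_channels)
  d <- dim(x)
  out <- cpp_cnn_predict(model$W, model$b, as.numeric(x), as.integer(d),
                         as.integer(batch_size))
  hw <- d[1] * d[2]
  lapply(seq_len(d[4]), function(i) {
    clip01(matrix(out[((i - 1) * hw + 1):(i * hw)], d[1], d[2]))
  })
}

#' Extract intermediate feature maps
#'
#' Returns the post-activation maps of one convolution layer for a single
#' patch, one `h x w` matrix per filter — the maps used to inspect which
#' branch the fusion network relies on where.
#'
#' @param model a `"hw_model"`.
#' @param patch a single input patch.
#' @param layer_index layer number (1 to 6).
#' @return list of `h x w` activation matrices (length = filters at layer).
#' @export
export_feature_maps <- function(model, patch, layer_index) {
  stopifnot(inherits(model, "hw_model"))
  layer_index <- as.integer(layer_index)
  n_layers <- length(model$spec$filters)
  if (is.na(layer_index) || layer_index < 1L || layer_index > n_layers) {
    stop(sprintf("layer_index must be between 1 and %d", n_layers), call. = FALSE)
  }
  x <- .stack_patches(list(patch), model$spec$in_channels)
  d <- dim(x)
  a <- cpp_cnn_activations(model$W, model$b, as.numeric(x),
                           as.integer(d), layer_index)
  lapply(seq_len(dim(a)[3]), function(k) a[, , k])
}

# portable checkpoint helpers -------------------------------------------------

#' Save / load model checkpoints
#'
#' Checkpoints are stored as RDS files holding the plain weight matrices,
#' biases, spec and loss history.
#'
#' @param model a `"hw_model"`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "hw_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "hw_model")
}
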
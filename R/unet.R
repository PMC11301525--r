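#' U-net configuration
#'
#' Architecture and optimisation settings for the mass/background pixel
#' classifier: a canonical encoder-decoder with skip connections, two 3x3
#' same-padded convolutions (ReLU) per level, 2x2 max pooling between
#' encoder levels, 2x2 stride-2 transposed convolutions in the decoder, and
#' a final 1x1 convolution to two classes with per-pixel softmax. Training
#' minimises per-pixel two-class cross-entropy with Adam.
#'
#' @param input_size Input side in pixels; must be divisible by
#'   `2^depth`.
#' @param depth Number of encoder levels (downsamplings).
#' @param base_filters Channels at the first level; doubled per level.
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum training epochs.
#' @param minibatch_size Samples per gradient step.
#' @param seed Integer seed controlling weight initialisation and shuffling.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(input_size = 256, depth = 4, base_filters = 32,
                        learning_rate = 0.001, max_epochs = 120,
                        minibatch_size = 12, seed = 1L) {
  cfg <- list(input_size = as.integer(input_size), depth = as.integer(depth),
              base_filters = as.integer(base_filters),
              learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
              minibatch_size = as.integer(minibatch_size), seed = as.integer(seed))
  if (any(unlist(cfg[c("input_size", "depth", "base_filters", "max_epochs",
                       "minibatch_size")]) < 0) ||
      cfg$depth < 1 || cfg$base_filters < 1 || cfg$minibatch_size < 1 ||
      cfg$learning_rate <= 0)
    stop("all U-net configuration counts must be positive")
  if (cfg$input_size %% (2^cfg$depth) != 0)
    stop(sprintf("input_size %d is not divisible by 2^depth = %d",
                 cfg$input_size, 2^cfg$depth))
  structure(cfg, class = "unet_config")
}

#' Reduced U-net profile for desk-scale CPU runs
#'
#' 128 x 128 inputs, two encoder levels, 8 base filters. The optimiser
#' settings are unchanged.
#'
#' @param max_epochs Training epochs for the profile.
#' @param seed Integer seed.
#' @export
unet_test_profile <- function(max_epochs = 3, seed = 1L) {
  unet_config(input_size = 128, depth = 2, base_filters = 8,
              max_epochs = max_epochs, seed = seed)
}

# Canonical weight order shared with the compiled kernels; see src/unet.cpp.
unet_weight_shapes <- function(depth, base) {
  f <- base * 2^(0:depth)
  shapes <- list()
  add <- function(name, nr, nc, fan) {
    shapes[[name]] <<- list(dim = c(nr, nc), fan_in = fan)
  }
  cin <- 1
  for (l in seq_len(depth)) {
    add(sprintf("enc%d_Wa", l - 1), 9 * cin, f[l], 9 * cin)
    add(sprintf("enc%d_ba", l - 1), f[l], 0, NA)
    add(sprintf("enc%d_Wb", l - 1), 9 * f[l], f[l], 9 * f[l])
    add(sprintf("enc%d_bb", l - 1), f[l], 0, NA)
    cin <- f[l]
  }
  add("bot_Wa", 9 * f[depth], f[depth + 1], 9 * f[depth])
  add("bot_ba", f[depth + 1], 0, NA)
  add("bot_Wb", 9 * f[depth + 1], f[depth + 1], 9 * f[depth + 1])
  add("bot_bb", f[depth + 1], 0, NA)
  for (l in rev(seq_len(depth))) {   # level depth-1 first
    add(sprintf("dec%d_Wu", l - 1), 4 * f[l + 1], f[l], f[l + 1])
    add(sprintf("dec%d_bu", l - 1), f[l], 0, NA)
    add(sprintf("dec%d_Wa", l - 1), 9 * 2 * f[l], f[l], 9 * 2 * f[l])
    add(sprintf("dec%d_ba", l - 1), f[l], 0, NA)
    add(sprintf("dec%d_Wb", l - 1), 9 * f[l], f[l], 9 * f[l])
    add(sprintf("dec%d_bb", l - 1), f[l], 0, NA)
  }
  add("final_W", f[1], 2, f[1])
  add("final_b", 2, 0, NA)
  shapes
}

#' Build an untrained U-net
#'
#' Weights use He initialisation (zero biases), drawn under the
#' configuration seed so two builds from the same configuration are
#' identical.
#'
#' @param config A [unet_config()].
#' @return An object of class `adx_unet` holding the weights, the
#'   configuration, and the (empty) training history.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  shapes <- unet_weight_shapes(config$depth, config$base_filters)
  weights <- local_seed(config$seed, {
    lapply(shapes, function(s) {
      if (s$dim[2] == 0) {                       # bias
        rep(0, s$dim[1])
      } else {
        matrix(rnorm(prod(s$dim), sd = sqrt(2 / s$fan_in)), s$dim[1], s$dim[2])
      }
    })
  })
  structure(list(config = config, weights = weights,
                 history = data.frame(epoch = integer(), loss = numeric()),
                 opt_state = NULL, trained_epochs = 0L),
            class = "adx_unet")
}

#' Number of trainable parameters of a U-net
#'
#' @param model An `adx_unet` (or a `unet_config`).
#' @export
unet_param_count <- function(model) {
  if (inherits(model, "unet_config"))
    model <- list(weights = lapply(
      unet_weight_shapes(model$depth, model$base_filters),
      function(s) numeric(max(1, s$dim[1]) * max(1, s$dim[2]))))
  sum(vapply(model$weights, length, 1L))
}

#' Train a U-net on image/mask samples
#'
#' Optimises per-pixel two-class cross-entropy with Adam at the configured
#' learning rate and minibatch size, with seeded shuffling each epoch.
#' Typically the samples are the 12-fold augmented training set from
#' [augment_pair()].
#'
#' @param model An `adx_unet` from [build_unet()].
#' @param samples List of samples, each a list with `image` (numeric matrix,
#'   `input_size` square, values in `[0, 1]`) and `mask` (logical/0-1).
#' @param epochs Number of epochs to run (default: the configured
#'   `max_epochs`); 0 returns the model unchanged with empty history.
#' @param verbose Print the per-epoch loss?
#' @return The trained model; `model$history` holds the per-epoch mean
#'   minibatch loss.
#' @export
unet_train <- function(model, samples, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "adx_unet"))
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$max_epochs
  if (epochs == 0) {
    model$history <- data.frame(epoch = integer(), loss = numeric())
    return(model)
  }
  if (!length(samples)) stop("cannot train on an empty sample list")
  n <- cfg$input_size
  imgs <- lapply(samples, function(s) {
    if (!all(dim(s$image) == c(n, n)))
      stop(sprintf("training image is not %d x %d", n, n))
    s$image
  })
  tgts <- lapply(samples, function(s) {
    m <- as_binary_matrix(s$mask)
    if (!all(dim(m) == c(n, n)))
      stop(sprintf("training mask is not %d x %d", n, n))
    m
  })

  w <- model$weights
  st <- model$opt_state
  if (is.null(st))
    st <- list(m = lapply(w, function(x) x * 0),
               v = lapply(w, function(x) x * 0), t = 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(), loss = numeric())

  local_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(imgs))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$minibatch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        res <- unet_batch_grad_cpp(imgs[idx], tgts[idx], w,
                                   cfg$depth, cfg$base_filters)
        g <- res$grads
        st$t <- st$t + 1
        corr <- sqrt(1 - b2^st$t) / (1 - b1^st$t)
        for (k in seq_along(w)) {
          st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g[[k]]
          st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g[[k]]^2
          w[[k]] <- w[[k]] - cfg$learning_rate * corr *
            st$m[[k]] / (sqrt(st$v[[k]]) + eps)
        }
        losses[bi] <- res$loss
      }
      history <- rbind(history,
                       data.frame(epoch = model$trained_epochs + ep,
                                  loss = mean(losses)))
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f", model$trained_epochs + ep,
                        mean(losses)))
    }
  })
  model$weights <- w
  model$opt_state <- st
  model$history <- history
  model$trained_epochs <- model$trained_epochs + as.integer(epochs)
  model
}

#' Predict the in-mass probability map for one ROI
#'
#' @param model A trained `adx_unet`.
#' @param roi Numeric matrix of the configured input size, values in
#'   `[0, 1]`.
#' @return List with `prob` (per-pixel P(mass)) and `mask` (`prob > 0.5`;
#'   with two softmax-normalised classes this equals the argmax rule).
#' @export
unet_predict <- function(model, roi) {
  stopifnot(inherits(model, "adx_unet"))
  n <- model$config$input_size
  if (!all(dim(roi) == c(n, n)))
    stop(sprintf("ROI must be %d x %d for this model", n, n))
  prob <- unet_predict_cpp(as_gray_matrix(roi, "roi"), model$weights,
                           model$config$depth, model$config$base_filters)
  list(prob = prob, mask = prob > 0.5)
}

#' Save / load a U-net checkpoint (weights + configuration)
#'
#' @param model An `adx_unet`.
#' @param path Checkpoint file path.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "adx_unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "adx_unet"))
  model
}
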
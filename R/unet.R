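# Structure predictor: a compact U-net regressor that maps a (residual)
# noise image to the structural component hidden inside it. Encoder-decoder
# with skip concatenations, `depth` pooling stages, filters doubling per
# stage from `base_filters`, no batch normalisation, two 3x3 conv + ReLU
# blocks per stage, nearest-neighbour upsampling followed by a 3x3
# convolution on the way up, and a linear 1x1 output head (regression in
# HU). Trained with Adam on an L1 loss. The conv/pool/upsample forward and
# backward passes live in compiled code; this file orchestrates them.

#' Configure the structure-predictor network
#'
#' @param depth Number of pooling levels (default 4).
#' @param base_filters Filters at the first level (default 32, doubling per
#'   pooling stage).
#' @param kernel_size Convolution kernel size (odd; default 3).
#' @param batch_norm Must be `FALSE`: the architecture deliberately omits
#'   batch normalisation.
#' @param activation Hidden activation (`"relu"`).
#' @param patch_size_px Side of the square training patches; must be
#'   divisible by `2^depth`.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed controlling initialisation, shuffling, patch
#'   draws and augmentation.
#' @return An object of class `model_config`.
#' @export
model_config <- function(depth = 4, base_filters = 32, kernel_size = 3,
                         batch_norm = FALSE, activation = "relu",
                         patch_size_px = 96, batch_size = 8, epochs = 10,
                         learning_rate = 1e-3, seed = 1) {
  if (depth < 1) stop("`depth` must be at least 1", call. = FALSE)
  if (base_filters < 1) stop("`base_filters` must be at least 1", call. = FALSE)
  if (kernel_size %% 2 != 1 || kernel_size < 1)
    stop("`kernel_size` must be odd", call. = FALSE)
  if (isTRUE(batch_norm))
    stop("batch normalisation is not part of this architecture", call. = FALSE)
  if (!identical(activation, "relu"))
    stop("only the 'relu' activation is supported", call. = FALSE)
  if (patch_size_px %% 2^depth != 0)
    stop("`patch_size_px` must be divisible by 2^depth", call. = FALSE)
  if (batch_size < 1 || epochs < 1 || learning_rate <= 0)
    stop("invalid training hyperparameters", call. = FALSE)
  structure(
    list(depth = as.integer(depth), base_filters = as.integer(base_filters),
         kernel_size = as.integer(kernel_size), batch_norm = FALSE,
         activation = "relu", patch_size_px = as.integer(patch_size_px),
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         learning_rate = as.numeric(learning_rate), seed = as.integer(seed)),
    class = "model_config")
}

# Layer recipe: ordered list of conv layers with (in, out, kernel) channels.
unet_layer_recipe <- function(config) {
  d <- config$depth; f <- config$base_filters; k <- config$kernel_size
  filt <- f * 2^(0:d)        # filt[i] = channels at stage i (1-based)
  layers <- list()
  add <- function(cin, cout, kk, tag) {
    layers[[length(layers) + 1]] <<- list(cin = cin, cout = cout, k = kk,
                                          tag = tag)
  }
  for (i in seq_len(d)) {
    cin <- if (i == 1) 1 else filt[i - 1]
    add(cin, filt[i], k, sprintf("enc%d_a", i))
    add(filt[i], filt[i], k, sprintf("enc%d_b", i))
  }
  add(filt[d], filt[d + 1], k, "bottleneck_a")
  add(filt[d + 1], filt[d + 1], k, "bottleneck_b")
  for (i in rev(seq_len(d))) {
    cin_up <- if (i == d) filt[d + 1] else filt[i + 1]
    add(cin_up, filt[i], k, sprintf("up%d", i))
    add(2 * filt[i], filt[i], k, sprintf("dec%d_a", i))
    add(filt[i], filt[i], k, sprintf("dec%d_b", i))
  }
  add(filt[1], 1, 1, "head")
  layers
}

#' Build an untrained structure predictor
#'
#' Initialises He-normal weights deterministically from `config$seed`.
#'
#' @param config A [model_config()].
#' @return An object of class `structure_predictor`.
#' @export
build_model <- function(config = model_config()) {
  if (!inherits(config, "model_config"))
    stop("`config` must be a model_config", call. = FALSE)
  recipe <- unet_layer_recipe(config)
  weights <- with_seed(derive_seed(config$seed, 97), lapply(recipe, function(l) {
    fan_in <- l$cin * l$k^2
    list(W = matrix(rnorm(l$cout * fan_in, sd = sqrt(2 / fan_in)),
                    l$cout, fan_in),
         b = numeric(l$cout), k = l$k)
  }))
  structure(
    list(weights = weights, config = config,
         normalization = list(scale = 100, shift = 0),
         trained = FALSE, history = NULL, recipe = recipe),
    class = "structure_predictor")
}

#' Number of trainable parameters
#' @param model A `structure_predictor`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, function(w) length(w$W) + length(w$b), 0))
}

#' @export
print.structure_predictor <- function(x, ...) {
  cat(sprintf(
    "<structure_predictor> depth %d, base filters %d, %s, %d parameters\n",
    x$config$depth, x$config$base_filters,
    if (x$trained) "trained" else "untrained", n_parameters(x)))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

relu_fwd <- function(y) {
  mask <- y > 0
  y[!mask] <- 0
  list(a = y, mask = mask)
}

# Forward pass over an H x W x 1 array (normalised units). When
# `keep = TRUE` an op tape with caches is returned for backprop.
unet_fwd <- function(model, x, keep = FALSE) {
  d <- model$config$depth
  w <- model$weights
  tape <- list()
  push <- function(entry) tape[[length(tape) + 1]] <<- entry
  li <- 0
  conv_block <- function(h, relu = TRUE) {
    li <<- li + 1
    if (keep) {
      fc <- cpp_conv_fwd_cache(h, w[[li]]$W, w[[li]]$b, w[[li]]$k)
      y <- fc$y
      cin <- dim(h)[3]
      if (relu) {
        r <- relu_fwd(y)
        push(list(type = "cr", l = li, col = fc$col, cin = cin,
                  mask = r$mask))
        r$a
      } else {
        push(list(type = "cl", l = li, col = fc$col, cin = cin))
        y
      }
    } else {
      y <- cpp_conv_fwd(h, w[[li]]$W, w[[li]]$b, w[[li]]$k)
      if (relu) relu_fwd(y)$a else y
    }
  }
  skips <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    h <- conv_block(h)
    h <- conv_block(h)
    skips[[i]] <- h
    mp <- cpp_maxpool_fwd(h)
    if (keep) push(list(type = "pool", i = i, idx = mp$idx))
    h <- mp$y
  }
  h <- conv_block(h)
  h <- conv_block(h)
  for (i in rev(seq_len(d))) {
    h <- cpp_upsample_fwd(h)
    if (keep) push(list(type = "up"))
    h <- conv_block(h)
    c1 <- dim(h)[3]
    h <- array(c(h, skips[[i]]), dim = c(dim(h)[1], dim(h)[2],
                                         c1 + dim(skips[[i]])[3]))
    if (keep) push(list(type = "cat", i = i, c1 = c1))
    h <- conv_block(h)
    h <- conv_block(h)
  }
  h <- conv_block(h, relu = FALSE)
  list(out = h, tape = if (keep) tape else NULL)
}

# Backward pass: walks the tape in reverse, returning per-layer gradients.
unet_bwd <- function(model, fwd, d_out) {
  w <- model$weights
  grads <- lapply(w, function(l) list(W = l$W * 0, b = l$b * 0))
  d_skip <- list()
  d <- d_out
  for (e in rev(fwd$tape)) {
    if (e$type == "cr" || e$type == "cl") {
      if (e$type == "cr") d <- d * e$mask
      g <- cpp_conv_bwd(e$col, w[[e$l]]$W, d, w[[e$l]]$k, e$cin)
      grads[[e$l]]$W <- grads[[e$l]]$W + g$dW
      grads[[e$l]]$b <- grads[[e$l]]$b + g$db
      d <- g$dX
    } else if (e$type == "cat") {
      nc <- dim(d)[3]
      d_skip[[e$i]] <- d[, , (e$c1 + 1):nc, drop = FALSE]
      d <- d[, , seq_len(e$c1), drop = FALSE]
    } else if (e$type == "up") {
      d <- cpp_upsample_bwd(d)
    } else if (e$type == "pool") {
      d <- cpp_maxpool_bwd(d, e$idx)
      d <- d + d_skip[[e$i]]
    }
  }
  grads
}

# ---- training --------------------------------------------------------------

draw_patch <- function(z, s, patch, flips = TRUE) {
  H <- nrow(z); W <- ncol(z)
  if (H < patch || W < patch) {
    z <- pad_reflect(z, max(0, patch - H), max(0, patch - W))
    s <- pad_reflect(s, max(0, patch - H), max(0, patch - W))
    H <- nrow(z); W <- ncol(z)
  }
  i0 <- sample.int(H - patch + 1, 1)
  j0 <- sample.int(W - patch + 1, 1)
  zi <- z[i0:(i0 + patch - 1), j0:(j0 + patch - 1)]
  si <- s[i0:(i0 + patch - 1), j0:(j0 + patch - 1)]
  if (flips) {
    if (runif(1) < 0.5) { zi <- zi[patch:1, ]; si <- si[patch:1, ] }
    if (runif(1) < 0.5) { zi <- zi[, patch:1]; si <- si[, patch:1] }
  }
  list(z = zi, s = si)
}

center_patch <- function(m, patch) {
  H <- nrow(m); W <- ncol(m)
  if (H < patch || W < patch)
    m <- pad_reflect(m, max(0, patch - H), max(0, patch - W))
  i0 <- floor((nrow(m) - patch) / 2) + 1
  j0 <- floor((ncol(m) - patch) / 2) + 1
  m[i0:(i0 + patch - 1), j0:(j0 + patch - 1)]
}

#' Train the structure predictor
#'
#' Minimises the mean absolute error between the predicted and true
#' structural components with Adam, drawing one random (optionally flipped)
#' patch per pair per epoch. Validation L1 is evaluated each epoch on fixed
#' centre patches of the validation pairs; the returned model carries the
#' best-validation weights. Deterministic given `config$seed`.
#'
#' @param model A `structure_predictor` from [build_model()] (or a
#'   [model_config()], from which one is built).
#' @param dataset A `training_set` from [build_training_set()], or a list of
#'   pairs with elements `z`, `s` and `meta$split`.
#' @param epochs Optional override of `config$epochs`.
#' @param augment Apply random horizontal/vertical flips to training
#'   patches (disable for fixed-sample optimisation checks).
#' @param verbose Print per-epoch losses.
#' @return The trained `structure_predictor`, with a `history` tibble
#'   (epoch, train_l1_hu, val_l1_hu, best_val_l1_hu).
#' @export
train_predictor <- function(model, dataset, epochs = NULL, augment = TRUE,
                            verbose = FALSE) {
  if (inherits(model, "model_config")) model <- build_model(model)
  if (!inherits(model, "structure_predictor"))
    stop("`model` must be a structure_predictor", call. = FALSE)
  pairs <- if (inherits(dataset, "training_set")) dataset$pairs else dataset
  if (length(pairs) == 0) stop("dataset is empty", call. = FALSE)
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  splits <- vapply(pairs, function(p) p$meta$split %||% "train", "")
  train_idx <- which(splits != "val")
  val_idx <- which(splits == "val")
  if (length(train_idx) == 0) stop("no training pairs", call. = FALSE)
  scale <- model$normalization$scale

  w <- model$weights
  mom <- lapply(w, function(l) list(W = l$W * 0, b = l$b * 0))
  vel <- lapply(w, function(l) list(W = l$W * 0, b = l$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  t_step <- 0

  eval_val <- function(w_now) {
    mdl <- model; mdl$weights <- w_now
    idx <- if (length(val_idx) > 0) val_idx else train_idx
    mean(vapply(idx, function(i) {
      zi <- center_patch(pairs[[i]]$z, cfg$patch_size_px) / scale
      si <- center_patch(pairs[[i]]$s, cfg$patch_size_px) / scale
      out <- unet_fwd(mdl, array(zi, c(dim(zi), 1)))$out
      mean(abs(out[, , 1] - si)) * scale
    }, 0))
  }

  history <- list()
  best_val <- Inf
  best_w <- w
  with_seed(derive_seed(cfg$seed, 11), {
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0; ep_n <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        bidx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
        gsum <- NULL
        bloss <- 0
        for (i in bidx) {
          pt <- draw_patch(pairs[[i]]$z, pairs[[i]]$s, cfg$patch_size_px,
                           flips = augment)
          zi <- array(pt$z / scale, c(cfg$patch_size_px, cfg$patch_size_px, 1))
          si <- pt$s / scale
          mdl <- model; mdl$weights <- w
          fwd <- unet_fwd(mdl, zi, keep = TRUE)
          r <- fwd$out[, , 1] - si
          bloss <- bloss + mean(abs(r))
          d_out <- array(sign(r) / length(r), dim = dim(fwd$out))
          g <- unet_bwd(mdl, fwd, d_out)
          gsum <- if (is.null(gsum)) g else
            Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), gsum, g)
        }
        nb <- length(bidx)
        bloss <- bloss / nb
        if (!is.finite(bloss))
          stop("training diverged (non-finite loss)", call. = FALSE)
        ep_loss <- ep_loss + bloss * nb; ep_n <- ep_n + nb
        t_step <- t_step + 1
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (l in seq_along(w)) {
          gW <- gsum[[l]]$W / nb; gb <- gsum[[l]]$b / nb
          mom[[l]]$W <- beta1 * mom[[l]]$W + (1 - beta1) * gW
          mom[[l]]$b <- beta1 * mom[[l]]$b + (1 - beta1) * gb
          vel[[l]]$W <- beta2 * vel[[l]]$W + (1 - beta2) * gW^2
          vel[[l]]$b <- beta2 * vel[[l]]$b + (1 - beta2) * gb^2
          w[[l]]$W <- w[[l]]$W -
            lr * (mom[[l]]$W / corr1) / (sqrt(vel[[l]]$W / corr2) + eps)
          w[[l]]$b <- w[[l]]$b -
            lr * (mom[[l]]$b / corr1) / (sqrt(vel[[l]]$b / corr2) + eps)
        }
      }
      val_l1 <- eval_val(w)
      if (!is.finite(val_l1))
        stop("training diverged (non-finite loss)", call. = FALSE)
      if (val_l1 < best_val) {
        best_val <- val_l1
        best_w <- w
      }
      history[[ep]] <- tibble(
        epoch = ep, train_l1_hu = ep_loss / ep_n * scale,
        val_l1_hu = val_l1, best_val_l1_hu = best_val)
      if (verbose)
        message(sprintf("epoch %d: train L1 %.3f HU, val L1 %.3f HU",
                        ep, ep_loss / ep_n * scale, val_l1))
    }
  })
  model$weights <- best_w
  model$trained <- TRUE
  model$history <- do.call(rbind, history)
  model
}

#' Per-epoch training history
#' @param model A trained `structure_predictor`.
#' @return Tibble with per-epoch train/validation L1 (HU).
#' @export
training_history <- function(model) model$history

#' Mean absolute prediction error over a set of pairs
#'
#' Recomputes `mean |s - f(z)|` (in HU) from full-image predictions;
#' useful as an independent check on reported losses.
#'
#' @param model A `structure_predictor`.
#' @param pairs A `training_set` or list of pairs.
#' @return Mean L1 in HU.
#' @export
evaluate_l1 <- function(model, pairs) {
  if (inherits(pairs, "training_set")) pairs <- pairs$pairs
  mean(vapply(pairs, function(p) {
    pred <- predict_structure(model, p$z)$pixels
    mean(abs(pred - p$s))
  }, 0))
}

#' Predict the structural component in a residual-noise image
#'
#' Reflect-pads the input to a multiple of `2^depth`, runs the network on
#' the full grid (convolutions are shift-equivariant, so full-image
#' inference matches patch training), and crops back. Deterministic.
#'
#' @param model A `structure_predictor`.
#' @param residual A [noise_image()] or numeric matrix (finite values).
#' @return A predicted [structure_component()] of the same shape.
#' @export
predict_structure <- function(model, residual) {
  if (!inherits(model, "structure_predictor"))
    stop("`model` must be a structure_predictor", call. = FALSE)
  m <- as_pixel_matrix(residual)
  if (!all(is.finite(m)))
    stop("residual contains non-finite values", call. = FALSE)
  H <- nrow(m); W <- ncol(m)
  mult <- 2^model$config$depth
  Hp <- ceiling(H / mult) * mult
  Wp <- ceiling(W / mult) * mult
  mp <- pad_reflect(m / model$normalization$scale, Hp - H, Wp - W)
  out <- unet_fwd(model, array(mp, c(Hp, Wp, 1)))$out[, , 1]
  pred <- out[seq_len(H), seq_len(W), drop = FALSE] *
    model$normalization$scale
  src <- if (inherits(residual, "noise_image")) residual$source_id else "input"
  structure_component(pred, predicted = TRUE, source_id = src)
}

# ---- persistence -----------------------------------------------------------

config_fingerprint <- function(config)
  paste(deparse(unclass(config)), collapse = "")

#' Save / load a trained structure predictor
#'
#' Single-file checkpoint holding weights, configuration, normalisation
#' constants and training history; the configuration fingerprint is
#' verified on load, and round-tripping preserves predictions bit-exactly.
#'
#' @param model A `structure_predictor`.
#' @param path File path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "structure_predictor"))
    stop("`model` must be a structure_predictor", call. = FALSE)
  payload <- list(format = "ctaudit_checkpoint_v1",
                  config = model$config,
                  fingerprint = config_fingerprint(model$config),
                  normalization = model$normalization,
                  weights = model$weights, trained = model$trained,
                  history = model$history)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("failed to read checkpoint '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(payload) ||
      !identical(payload$format, "ctaudit_checkpoint_v1"))
    stop("not a ctaudit checkpoint: ", path, call. = FALSE)
  if (!identical(payload$fingerprint, config_fingerprint(payload$config)))
    stop("checkpoint config fingerprint mismatch", call. = FALSE)
  model <- build_model(payload$config)
  if (length(payload$weights) != length(model$weights))
    stop("checkpoint weights do not match the declared architecture",
         call. = FALSE)
  model$weights <- payload$weights
  model$normalization <- payload$normalization
  model$trained <- isTRUE(payload$trained)
  model$history <- payload$history
  model
}
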
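# Epithelium / necrosis segmentation.
#
# A desk-scale pixelwise segmenter in the encoder-decoder spirit: each
# channel is smoothed at several spatial scales (the downsampling/upsampling
# context path) and concatenated with the native-resolution channels (the
# skip connection); a small MLP head maps the per-pixel feature vector to a
# foreground probability. Trained by seeded minibatch SGD on per-pixel mean
# squared error with inverted-dropout on the hidden layer and a geometric
# learning-rate schedule.

#' Segmentation model configuration
#'
#' Defaults mirror a full-scale training recipe (300 epochs, learning rate
#' 1e-2 decayed geometrically to 1e-5, dropout keep 0.8, minibatch 64);
#' tests and examples pass far fewer epochs.
#'
#' @param input_size expected patch side in pixels (metadata; prediction
#'   works on any size since the model is pixelwise).
#' @param epochs training epochs, >= 1.
#' @param initial_lr,final_lr learning-rate schedule endpoints,
#'   `initial_lr >= final_lr > 0`.
#' @param dropout_keep keep probability for hidden units in (0, 1\].
#' @param batch_size minibatch size in pixels.
#' @param augmentations subset of `c("horizontal_flip", "vertical_flip",
#'   "rotation")` applied to training patches.
#' @param hidden_units width of the MLP hidden layer.
#' @param pixels_per_image pixels sampled from each patch per epoch.
#' @param blur_sigmas smoothing scales (px) of the context pyramid.
#' @param seed RNG seed for reproducible training.
#' @return A `segmenter_config` list.
#' @export
segmenter_config <- function(input_size = 256L, epochs = 300L,
                             initial_lr = 1e-2, final_lr = 1e-5,
                             dropout_keep = 0.8, batch_size = 64L,
                             augmentations = c("horizontal_flip", "vertical_flip"),
                             hidden_units = 8L, pixels_per_image = 512L,
                             blur_sigmas = c(2, 6), seed = 1L) {
  if (epochs < 1) abort("epochs must be >= 1", class = "pdl1ic_value_error")
  if (!(dropout_keep > 0 && dropout_keep <= 1)) {
    abort("dropout_keep must lie in (0, 1]", class = "pdl1ic_value_error")
  }
  if (!(initial_lr >= final_lr && final_lr > 0)) {
    abort("require initial_lr >= final_lr > 0", class = "pdl1ic_value_error")
  }
  augmentations <- match.arg(augmentations,
                             c("horizontal_flip", "vertical_flip", "rotation"),
                             several.ok = TRUE)
  structure(list(input_size = as.integer(input_size), epochs = as.integer(epochs),
                 initial_lr = initial_lr, final_lr = final_lr,
                 dropout_keep = dropout_keep, batch_size = as.integer(batch_size),
                 augmentations = augmentations,
                 hidden_units = as.integer(hidden_units),
                 pixels_per_image = as.integer(pixels_per_image),
                 blur_sigmas = blur_sigmas, seed = as.integer(seed)),
            class = "segmenter_config")
}

# Per-pixel feature matrix: native R,G,B plus each channel smoothed at the
# configured sigmas, all scaled to [0,1].
segmenter_features <- function(patch, blur_sigmas) {
  px <- patch$pixels / 255
  feats <- list(px[, , 1], px[, , 2], px[, , 3])
  for (sg in blur_sigmas) {
    for (ch in 1:3) {
      img <- EBImage::Image(px[, , ch])
      feats[[length(feats) + 1]] <- EBImage::imageData(EBImage::gblur(img, sigma = sg))
    }
  }
  do.call(cbind, lapply(feats, as.vector))
}

apply_augmentation <- function(px, bits, augmentations) {
  if ("horizontal_flip" %in% augmentations && runif(1) < 0.5) {
    px <- px[, rev(seq_len(ncol(bits))), , drop = FALSE]
    bits <- bits[, rev(seq_len(ncol(bits))), drop = FALSE]
  }
  if ("vertical_flip" %in% augmentations && runif(1) < 0.5) {
    px <- px[rev(seq_len(nrow(bits))), , , drop = FALSE]
    bits <- bits[rev(seq_len(nrow(bits))), , drop = FALSE]
  }
  if ("rotation" %in% augmentations && runif(1) < 0.5) {
    rot <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
    px <- simplify2array(lapply(1:3, function(ch) rot(px[, , ch])))
    bits <- rot(bits)
  }
  list(px = px, bits = bits)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a pixelwise region segmenter
#'
#' @param examples list of `list(patch = rgb_patch, mask = binary_mask)`
#'   training pairs; at least two, masks matching patch dimensions.
#' @param config a [segmenter_config()].
#' @param role region role the model predicts (`"epithelium"` or
#'   `"necrotic"`); taken from the first mask when `NULL`.
#' @return A `segmenter_model` with learned weights and a per-epoch
#'   training-loss log.
#' @export
train_segmenter <- function(examples, config = segmenter_config(), role = NULL) {
  if (length(examples) < 2) {
    abort("train_segmenter needs at least 2 examples", class = "pdl1ic_value_error")
  }
  for (ex in examples) {
    stopifnot(inherits(ex$patch, "rgb_patch"), inherits(ex$mask, "binary_mask"))
    check_same_dim(ex$patch, ex$mask, "example patch/mask")
  }
  if (is.null(role)) role <- examples[[1]]$mask$role
  n_feat <- 3L * (1L + length(config$blur_sigmas))
  h <- config$hidden_units

  with_local_seed(config$seed, {
    W1 <- matrix(rnorm(n_feat * h, sd = 0.5), n_feat, h)
    b1 <- rnorm(h, sd = 0.1)
    W2 <- matrix(rnorm(h, sd = 0.5), h, 1)
    b2 <- 0
    loss_log <- numeric(config$epochs)
    lr_seq <- exp(seq(log(config$initial_lr), log(config$final_lr),
                      length.out = max(config$epochs, 2)))[seq_len(config$epochs)]
    for (ep in seq_len(config$epochs)) {
      lr <- lr_seq[ep]
      ep_loss <- 0; ep_batches <- 0
      for (ex in examples) {
        aug <- apply_augmentation(ex$patch$pixels, ex$mask$bits, config$augmentations)
        X <- segmenter_features(rgb_patch(aug$px), config$blur_sigmas)
        y <- as.numeric(as.vector(aug$bits))
        idx <- sample.int(length(y), min(config$pixels_per_image, length(y)))
        splits <- split(idx, ceiling(seq_along(idx) / config$batch_size))
        for (b in splits) {
          Xb <- X[b, , drop = FALSE]; yb <- y[b]
          Z1 <- sweep(Xb %*% W1, 2, b1, "+")
          A1 <- tanh(Z1)
          if (config$dropout_keep < 1) {
            keep <- matrix(runif(length(A1)) < config$dropout_keep,
                           nrow(A1), ncol(A1))
            A1 <- A1 * keep / config$dropout_keep
          }
          out <- sigmoid(as.vector(A1 %*% W2) + b2)
          err <- out - yb
          ep_loss <- ep_loss + mean(err^2); ep_batches <- ep_batches + 1
          dz2 <- 2 * err * out * (1 - out) / length(yb)
          gW2 <- crossprod(A1, dz2)
          gb2 <- sum(dz2)
          dA1 <- outer(dz2, as.vector(W2))
          dz1 <- dA1 * (1 - tanh(Z1)^2)
          gW1 <- crossprod(Xb, dz1)
          gb1 <- colSums(dz1)
          W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
          W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
        }
      }
      loss_log[ep] <- ep_loss / ep_batches
    }
    structure(list(role = role, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   blur_sigmas = config$blur_sigmas, config = config,
                   loss_log = loss_log),
              class = "segmenter_model")
  })
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf("<segmenter_model role=%s, %d->%d->1, %d epochs, final loss %.4g>\n",
              x$role, nrow(x$W1), ncol(x$W1), length(x$loss_log),
              x$loss_log[length(x$loss_log)]))
  invisible(x)
}

#' Per-pixel foreground probability map from a trained segmenter
#'
#' @param model a `segmenter_model`.
#' @param patch an `rgb_patch`.
#' @return Numeric H x W matrix of probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, patch) {
  stopifnot(inherits(model, "segmenter_model"), inherits(patch, "rgb_patch"))
  X <- segmenter_features(patch, model$blur_sigmas)
  A1 <- tanh(sweep(X %*% model$W1, 2, model$b1, "+"))
  p <- sigmoid(as.vector(A1 %*% model$W2) + model$b2)
  matrix(p, nrow = dim(patch)[1], ncol = dim(patch)[2])
}

#' Save / load a segmenter checkpoint directory
#'
#' Weights and configuration are stored as JSON in `dir`, one checkpoint
#' per region role.
#'
#' @param model a `segmenter_model`.
#' @param dir checkpoint directory.
#' @return `save_segmenter()` returns the file path invisibly;
#'   `load_segmenter()` returns a `segmenter_model`.
#' @export
save_segmenter <- function(model, dir) {
  stopifnot(inherits(model, "segmenter_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0("segmenter_", model$role, ".json"))
  payload <- list(role = model$role,
                  W1 = model$W1, b1 = model$b1,
                  W2 = as.vector(model$W2), b2 = model$b2,
                  blur_sigmas = model$blur_sigmas,
                  loss_log = model$loss_log)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_segmenter
#' @param role region role of the checkpoint to load.
#' @export
load_segmenter <- function(dir, role) {
  path <- file.path(dir, paste0("segmenter_", role, ".json"))
  if (!file.exists(path)) {
    abort(paste0("no checkpoint for role '", role, "' in ", dir),
          class = "pdl1ic_io_error")
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(role = p$role,
                 W1 = as.matrix(p$W1),
                 b1 = p$b1, W2 = matrix(p$W2, ncol = 1), b2 = p$b2,
                 blur_sigmas = p$blur_sigmas, config = NULL,
                 loss_log = p$loss_log),
            class = "segmenter_model")
}

# ---- Region providers -------------------------------------------------------

#' Region providers for the scoring pipeline
#'
#' A region provider answers [predict_regions()] with an epithelium and a
#' necrotic mask for a patch. `oracle_region_provider()` returns stored
#' ground-truth masks verbatim (for testing scoring independently of model
#' quality); `null_region_provider()` returns empty masks (no exclusion);
#' `segmenter_region_provider()` thresholds the probability maps of two
#' trained single-role models.
#'
#' @param epithelium,necrotic `binary_mask` objects with the matching roles.
#' @return A region provider object.
#' @export
oracle_region_provider <- function(epithelium, necrotic) {
  stopifnot(inherits(epithelium, "binary_mask"), inherits(necrotic, "binary_mask"))
  if (epithelium$role != "epithelium" || necrotic$role != "necrotic") {
    abort("oracle_region_provider requires roles epithelium and necrotic",
          class = "pdl1ic_value_error")
  }
  check_same_dim(epithelium, necrotic, "epithelium/necrotic masks")
  structure(list(epithelium = epithelium, necrotic = necrotic),
            class = c("oracle_region_provider", "region_provider"))
}

#' @rdname oracle_region_provider
#' @export
null_region_provider <- function() {
  structure(list(), class = c("null_region_provider", "region_provider"))
}

#' @rdname oracle_region_provider
#' @param epithelium_model,necrotic_model trained `segmenter_model`s for
#'   the two roles.
#' @export
segmenter_region_provider <- function(epithelium_model, necrotic_model) {
  for (m in list(epithelium_model, necrotic_model)) {
    if (!inherits(m, "segmenter_model") || is.null(m$W1)) {
      abort("segmenter_region_provider requires trained segmenter models",
            class = "pdl1ic_state_error")
    }
  }
  if (epithelium_model$role != "epithelium" || necrotic_model$role != "necrotic") {
    abort("models must have roles epithelium and necrotic",
          class = "pdl1ic_value_error")
  }
  structure(list(epithelium_model = epithelium_model,
                 necrotic_model = necrotic_model),
            class = c("segmenter_region_provider", "region_provider"))
}

#' Predict epithelium and necrotic masks for a patch
#'
#' @param provider a region provider.
#' @param patch an `rgb_patch`.
#' @param prob_threshold probability threshold for model-based providers;
#'   a pixel is set iff its probability is `>= prob_threshold`, so raising
#'   the threshold never adds pixels.
#' @return `list(epithelium = binary_mask, necrotic = binary_mask)`.
#' @export
predict_regions <- function(provider, patch, prob_threshold = 0.5) {
  UseMethod("predict_regions")
}

#' @export
predict_regions.oracle_region_provider <- function(provider, patch,
                                                   prob_threshold = 0.5) {
  check_same_dim(provider$epithelium, patch, "stored mask/patch")
  list(epithelium = provider$epithelium, necrotic = provider$necrotic)
}

#' @export
predict_regions.null_region_provider <- function(provider, patch,
                                                 prob_threshold = 0.5) {
  d <- dim(patch)
  empty <- matrix(FALSE, d[1], d[2])
  list(epithelium = binary_mask(empty, "epithelium"),
       necrotic = binary_mask(empty, "necrotic"))
}

#' @export
predict_regions.segmenter_region_provider <- function(provider, patch,
                                                      prob_threshold = 0.5) {
  pe <- predict_prob(provider$epithelium_model, patch)
  pn <- predict_prob(provider$necrotic_model, patch)
  list(epithelium = binary_mask(pe >= prob_threshold, "epithelium"),
       necrotic = binary_mask(pn >= prob_threshold, "necrotic"))
}

#' Intersection-over-union of two masks
#'
#' @param a,b `binary_mask` objects of equal dimensions.
#' @return IoU in \[0, 1\] (1 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_same_dim(a, b, "masks")
  uni <- sum(a$bits | b$bits)
  if (uni == 0) return(1)
  sum(a$bits & b$bits) / uni
}
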
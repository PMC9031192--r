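#' Convolutional-network architecture specification
#'
#' VGG-style layout: blocks of 3x3 stride-1 same-padding convolutions (ReLU),
#' each block followed by a 2x2 stride-2 max pool, then fully connected
#' layers and a softmax output.
#'
#' @param input_shape integer `c(height, width, channels)`; channels must be
#'   1 or 3 and height/width divisible by `2 ^ length(conv_blocks)`.
#' @param conv_blocks list of `c(layer_count, filter_count)` per block.
#' @param fc_sizes widths of the hidden fully connected layers.
#' @param n_classes output units (softmax width).
#' @return object of class `"architecture_spec"`.
#' @export
architecture_spec <- function(input_shape, conv_blocks, fc_sizes, n_classes) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3 || !input_shape[3] %in% c(1L, 3L))
    stopf("input_shape must be c(H, W, channels) with channels 1 or 3")
  nb <- length(conv_blocks)
  if (any(input_shape[1:2] %% 2L^nb != 0))
    stopf("input height/width must be divisible by 2^%d (one halving per pool)", nb)
  structure(list(input_shape = input_shape,
                 conv_blocks = lapply(conv_blocks, as.integer),
                 fc_sizes = as.integer(fc_sizes),
                 n_classes = as.integer(n_classes)),
            class = "architecture_spec")
}

# Compile an architecture into a flat layer list with resolved shapes.
compile_layers <- function(arch) {
  H <- arch$input_shape[1]; W <- arch$input_shape[2]; C <- arch$input_shape[3]
  layers <- list()
  for (blk in arch$conv_blocks) {
    for (i in seq_len(blk[1])) {
      layers[[length(layers) + 1]] <-
        list(type = "conv", c_in = C, c_out = blk[2], out_shape = c(H, W, blk[2]))
      C <- blk[2]
    }
    H <- H %/% 2L; W <- W %/% 2L
    layers[[length(layers) + 1]] <-
      list(type = "pool", out_shape = c(H, W, C))
  }
  layers[[length(layers) + 1]] <-
    list(type = "flatten", out_shape = H * W * C)
  n_in <- H * W * C
  for (s in arch$fc_sizes) {
    layers[[length(layers) + 1]] <-
      list(type = "fc", n_in = n_in, n_out = s, act = "relu", out_shape = s)
    n_in <- s
  }
  layers[[length(layers) + 1]] <-
    list(type = "fc", n_in = n_in, n_out = arch$n_classes, act = "linear",
         out_shape = arch$n_classes)
  layers
}

#' Trainable-parameter count of a model or architecture
#'
#' Walks the compiled layer list and sums the sizes of every weight and bias
#' tensor the model would allocate.
#'
#' @param x a `cnn_model` or an [architecture_spec()].
#' @return integer-valued count.
#' @export
count_parameters <- function(x) {
  layers <- if (inherits(x, "cnn_model")) x$layers else compile_layers(x)
  total <- 0
  for (ly in layers) {
    if (ly$type == "conv") total <- total + (9 * ly$c_in + 1) * ly$c_out
    if (ly$type == "fc")   total <- total + (ly$n_in + 1) * ly$n_out
  }
  total
}

#' Per-layer output shapes
#'
#' @param x a `cnn_model` or [architecture_spec()].
#' @return data.frame with layer type and output shape string.
#' @export
layer_shapes <- function(x) {
  layers <- if (inherits(x, "cnn_model")) x$layers else compile_layers(x)
  data.frame(
    layer = seq_along(layers),
    type = vapply(layers, `[[`, "", "type"),
    out_shape = vapply(layers, function(ly)
      paste(ly$out_shape, collapse = "x"), "")
  )
}

new_cnn_model <- function(arch, variant) {
  layers <- compile_layers(arch)
  structure(list(arch = arch, layers = layers, variant = variant,
                 weights = NULL, opt_state = NULL, classes = NULL,
                 channel_mode = NULL, history = NULL, seed = NULL,
                 param_count = count_parameters(arch)),
            class = "cnn_model")
}

#' Build the full VGG-16 classifier
#'
#' Canonical VGG-16 layout: five convolution blocks of 64/128/256/512/512
#' filters with 2-2-3-3-3 layers (all 3x3, stride 1, same padding), a 2x2
#' stride-2 max pool after each block, two fully connected layers and a
#' softmax output. In its canonical 224x224x3 / 1000-class / 4096-4096 form
#' this network has 138,357,544 trainable parameters (about 138 million).
#' Weights are not allocated until [init_weights()] or [train()] is called.
#'
#' @param input_shape `c(224, 224, channels)` with channels 1 or 3 (single
#'   channel for the grayscale spectral modes).
#' @param n_classes output classes (4 for the ear-condition study; 1000 for
#'   the canonical form).
#' @param fc_sizes hidden fully connected widths, default `c(4096, 4096)`.
#' @return a `cnn_model` with `$param_count` filled in.
#' @export
build_vgg16 <- function(input_shape = c(224, 224, 3), n_classes = 4,
                        fc_sizes = c(4096, 4096)) {
  arch <- architecture_spec(
    input_shape = input_shape,
    conv_blocks = list(c(2, 64), c(2, 128), c(3, 256), c(3, 512), c(3, 512)),
    fc_sizes = fc_sizes,
    n_classes = n_classes)
  new_cnn_model(arch, "vgg16")
}

#' Build the desk-scale tiny variant
#'
#' Same layout contract as [build_vgg16()] (3x3 stride-1 same-padding convs,
#' 2x2 stride-2 pools, ReLU, softmax) with reduced depth and width, trainable
#' on a single CPU in minutes. Defaults: 32x32 input, three blocks of
#' 8/16/32 filters (one conv each), one hidden FC of 64.
#'
#' @param input_shape `c(H, W, channels)`.
#' @param conv_blocks list of `c(layer_count, filters)`.
#' @param fc_sizes hidden FC widths.
#' @param n_classes output classes.
#' @return a `cnn_model`.
#' @export
build_tiny <- function(input_shape = c(32, 32, 1),
                       conv_blocks = list(c(1, 8), c(1, 16), c(1, 32)),
                       fc_sizes = 64, n_classes = 4) {
  arch <- architecture_spec(input_shape, conv_blocks, fc_sizes, n_classes)
  new_cnn_model(arch, "tiny")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model %s> input %s, %d classes, %s trainable parameters%s\n",
              x$variant, paste(x$arch$input_shape, collapse = "x"),
              x$arch$n_classes, format(x$param_count, big.mark = ","),
              if (is.null(x$weights)) " (weights not initialized)" else ""))
  invisible(x)
}

#' Initialize model weights (Glorot uniform, seeded)
#'
#' @param model a `cnn_model`.
#' @param seed integer seed.
#' @return the model with `$weights` and a fresh optimizer state.
#' @export
init_weights <- function(model, seed = 1L) {
  model$weights <- with_seed(seed, lapply(model$layers, function(ly) {
    if (ly$type == "conv") {
      fan_in <- 9 * ly$c_in; fan_out <- 9 * ly$c_out
      lim <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(runif(9 * ly$c_in * ly$c_out, -lim, lim),
                      9 * ly$c_in, ly$c_out),
           b = rep(0, ly$c_out))
    } else if (ly$type == "fc") {
      lim <- sqrt(6 / (ly$n_in + ly$n_out))
      list(W = matrix(runif(ly$n_in * ly$n_out, -lim, lim), ly$n_in, ly$n_out),
           b = rep(0, ly$n_out))
    } else NULL
  }))
  model$opt_state <- adam_init(model$weights)
  model$seed <- as.integer(seed)
  model
}

#' Training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 1e-5, batch
#' size 32, 100 epochs, on-the-fly augmentation (rotation, zoom, flips) on
#' training batches only, an 80/20 train/validation split, and 10 trials with
#' re-derived seeds. Desk-scale experiments on the tiny variant typically
#' override `learning_rate`, `epochs` and `batch_size`.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size samples per optimization step.
#' @param epochs full passes over the training split.
#' @param val_fraction validation share of the non-test data (0.2 = 80/20).
#' @param augment logical; apply on-the-fly augmentation to training batches.
#' @param rotation max absolute rotation in degrees (uniform in +/- range).
#' @param zoom max relative zoom (uniform in `1 +/- zoom`).
#' @param flip_h,flip_v allow horizontal / vertical flips (p = 0.5 each).
#' @param n_trials number of independent trials (re-split + re-init).
#' @param seed integer seed.
#' @return object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 32, epochs = 100,
                         val_fraction = 0.2, augment = TRUE, rotation = 15,
                         zoom = 0.1, flip_h = TRUE, flip_v = TRUE,
                         n_trials = 10, seed = 1L) {
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1)
    stopf("val_fraction must lie in (0, 1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), val_fraction = val_fraction,
                 augment = augment, rotation = rotation, zoom = zoom,
                 flip_h = flip_h, flip_v = flip_v,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "train_config")
}

# Augment one H x W x C array: flips, rotation, zoom (bilinear, zero fill).
augment_image <- function(img, cfg) {
  d <- dim(img)
  if (cfg$flip_h && runif(1) < 0.5) img <- img[, rev(seq_len(d[2])), , drop = FALSE]
  if (cfg$flip_v && runif(1) < 0.5) img <- img[rev(seq_len(d[1])), , , drop = FALSE]
  if (cfg$rotation > 0) {
    ang <- runif(1, -cfg$rotation, cfg$rotation)
    img <- as.array(EBImage::rotate(img, ang, output.dim = d[1:2], bg.col = 0))
    dim(img) <- d
  }
  if (cfg$zoom > 0) {
    z <- runif(1, 1 - cfg$zoom, 1 + cfg$zoom)
    nh <- max(2L, round(d[1] * z)); nw <- max(2L, round(d[2] * z))
    zi <- resize_image(img, nh, nw)
    dim(zi) <- c(nh, nw, d[3])
    out <- array(0, d)
    if (z >= 1) {
      oy <- (nh - d[1]) %/% 2L; ox <- (nw - d[2]) %/% 2L
      out <- zi[oy + seq_len(d[1]), ox + seq_len(d[2]), , drop = FALSE]
    } else {
      oy <- (d[1] - nh) %/% 2L; ox <- (d[2] - nw) %/% 2L
      out[oy + seq_len(nh), ox + seq_len(nw), ] <- zi
    }
    img <- out
    dim(img) <- d
  }
  img
}

# Stack a list of images into the model's input tensor: resize to the
# architecture's spatial size (bilinear), scale 0-255 -> 0-1.
prepare_batch <- function(images, input_shape) {
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  X <- array(0, c(H, W, C, length(images)))
  for (i in seq_along(images)) {
    img <- images[[i]]
    nch <- if (length(dim(img)) == 3) dim(img)[3] else 1L
    if (nch != C)
      stopf("image %d has %d channel(s) but the model expects %d; check that the spectral mode matches the architecture",
            i, nch, C)
    if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
    if (!all(dim(img)[1:2] == c(H, W))) {
      img <- resize_image(img, H, W)
      dim(img) <- c(H, W, C)
    }
    X[, , , i] <- img / 255
  }
  X
}

label_indices <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx))
    stopf("unknown label(s): %s", paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

# Stratified index split: fraction `frac` of each class into the first set.
stratified_split <- function(y, frac) {
  first <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n1 <- round(length(idx) * frac)
    first <- c(first, sample(idx, n1))
  }
  sort(first)
}

#' Train a CNN on labeled spectral images
#'
#' Resizes images to the architecture input, splits the data into stratified
#' training/validation parts, minimizes cross-entropy with Adam, and applies
#' on-the-fly augmentation to training batches only. Fully seeded: identical
#' model, data and config reproduce identical weights and history.
#'
#' @param model a `cnn_model` (weights initialized here if absent, from
#'   `cfg$seed`).
#' @param images list of pixel arrays (`H x W` for 1-channel modes,
#'   `H x W x 3` for 3-channel), values in 0-255.
#' @param labels class label per image.
#' @param cfg a [train_config()].
#' @param classes class-name order for the output units; default the unique
#'   labels in order of first appearance.
#' @param mode optional [channel_modes()] name to record on the model; its
#'   implied channel count must match the architecture.
#' @param val_images,val_labels optional explicit validation set; when given,
#'   all of `images` are used for training and no internal split is made.
#' @return the trained `cnn_model` with `$history` (per-epoch data.frame:
#'   `epoch`, `train_loss`, `train_acc`, `val_acc`).
#' @export
train <- function(model, images, labels, cfg = train_config(),
                  classes = NULL, mode = NULL,
                  val_images = NULL, val_labels = NULL) {
  if (!is.null(mode)) {
    if (mode_channels(mode) != model$arch$input_shape[3])
      stopf("mode '%s' implies %d channel(s) but architecture '%s' expects %d",
            mode, mode_channels(mode), model$variant, model$arch$input_shape[3])
    model$channel_mode <- mode
  }
  if (is.null(classes))
    classes <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  if (length(classes) != model$arch$n_classes)
    stopf("%d classes supplied but the model has %d output units",
          length(classes), model$arch$n_classes)
  y <- label_indices(labels, classes)
  model$classes <- classes

  with_seed(cfg$seed, {
    if (is.null(model$weights)) model <- init_weights(model, cfg$seed)
    n <- length(images)
    if (is.null(val_images)) {
      X_all <- prepare_batch(images, model$arch$input_shape)
      val_idx <- stratified_split(y, cfg$val_fraction)
      tr_idx <- setdiff(seq_len(n), val_idx)
    } else {
      y <- c(y, label_indices(val_labels, classes))
      X_all <- prepare_batch(c(images, val_images), model$arch$input_shape)
      tr_idx <- seq_len(n)
      val_idx <- n + seq_along(val_images)
    }
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          train_acc = numeric(0), val_acc = numeric(0))
    t_step <- 0L
    if (cfg$epochs > 0) {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample(tr_idx)
        ep_loss <- 0; ep_hits <- 0
        for (start in seq(1, length(ord), by = cfg$batch_size)) {
          bi <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
          Xb <- X_all[, , , bi, drop = FALSE]
          if (cfg$augment)
            for (k in seq_along(bi))
              Xb[, , , k] <- augment_image(
                array(Xb[, , , k], dim(Xb)[1:3]), cfg)
          yb <- y[bi]
          fwd <- cnn_forward(model, Xb)
          P <- fwd$probs
          ep_loss <- ep_loss -
            sum(log(pmax(P[cbind(seq_along(bi), yb)], 1e-12)))
          ep_hits <- ep_hits + sum(max.col(P) == yb)
          dlogits <- P
          dlogits[cbind(seq_along(bi), yb)] <-
            dlogits[cbind(seq_along(bi), yb)] - 1
          dlogits <- dlogits / length(bi)
          bwd <- cnn_backward(model, fwd, dlogits)
          t_step <- t_step + 1L
          upd <- adam_step(model$weights, bwd$grads, model$opt_state,
                           cfg$learning_rate, t_step)
          model$weights <- upd$weights
          model$opt_state <- upd$state
        }
        val_acc <- if (length(val_idx)) {
          Pv <- cnn_forward(model, X_all[, , , val_idx, drop = FALSE],
                            keep_cache = FALSE)$probs
          mean(max.col(Pv) == y[val_idx])
        } else NA_real_
        history <- rbind(history, data.frame(
          epoch = ep, train_loss = ep_loss / length(ord),
          train_acc = ep_hits / length(ord), val_acc = val_acc))
      }
    }
    model$history <- history
    model
  })
}

#' Class-probability predictions
#'
#' @param model a trained (or at least initialized) `cnn_model`.
#' @param images list of pixel arrays matching the model's channel count.
#' @return `n x n_classes` matrix; rows sum to 1; columns named by the
#'   model's classes when known.
#' @export
predict_proba <- function(model, images) {
  if (is.null(model$weights))
    stopf("model has no weights; call init_weights() or train() first")
  X <- prepare_batch(images, model$arch$input_shape)
  P <- cnn_forward(model, X, keep_cache = FALSE)$probs
  if (!is.null(model$classes)) colnames(P) <- model$classes
  P
}

#' Predicted class labels
#'
#' @param model a trained `cnn_model`.
#' @param images list of pixel arrays.
#' @return character vector of predicted class names (or integer indices when
#'   the model has no class names).
#' @export
predict_class <- function(model, images) {
  P <- predict_proba(model, images)
  idx <- max.col(P, ties.method = "first")
  if (is.null(model$classes)) idx else model$classes[idx]
}
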
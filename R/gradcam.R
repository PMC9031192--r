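#' Gradient-weighted class activation map
#'
#' Computes the gradient of the pre-softmax score of `target_class` with
#' respect to the feature maps of the last convolutional layer (the final
#' conv of the last block, before its pool), averages the gradient spatially
#' into per-channel weights, forms the weighted sum of the feature maps,
#' rectifies it, normalizes by its maximum and bilinearly upsamples to the
#' input resolution. Using the pre-softmax score makes the map invariant to
#' adding a constant to all logits and avoids softmax saturation zeroing the
#' gradients.
#'
#' @param model a trained `cnn_model`.
#' @param image one pixel array matching the model's channel count.
#' @param target_class class name or index.
#' @return object of class `"heatmap"`: list with `values` (input-resolution
#'   `H x W` matrix in `[0, 1]`), `coarse` (un-upsampled map), `target_class`,
#'   `layer` (index of the conv layer used) and `degenerate` (TRUE when the
#'   rectified map was identically zero; values left at 0, not normalized).
#' @export
grad_cam <- function(model, image, target_class) {
  if (is.null(model$weights))
    stopf("model has no weights; train it first")
  ci <- if (is.character(target_class)) {
    i <- match(target_class, model$classes)
    if (is.na(i)) stopf("unknown class '%s'", target_class)
    i
  } else as.integer(target_class)
  if (ci < 1 || ci > model$arch$n_classes) stopf("target_class out of range")

  conv_idx <- which(vapply(model$layers, `[[`, "", "type") == "conv")
  last_conv <- max(conv_idx)
  X <- prepare_batch(list(image), model$arch$input_shape)
  fwd <- cnn_forward(model, X)
  dlogits <- matrix(0, 1, model$arch$n_classes)
  dlogits[1, ci] <- 1
  bwd <- cnn_backward(model, fwd, dlogits, stop_layer = last_conv)
  A <- fwd$caches[[last_conv]]$A          # h x w x F x 1 post-ReLU features
  dA <- bwd$dA
  h <- dim(A)[1]; w <- dim(A)[2]; nf <- dim(A)[3]
  alpha <- apply(array(dA, c(h, w, nf)), 3, mean)  # global-average-pooled grads
  cam <- matrix(0, h, w)
  for (f in seq_len(nf)) cam <- cam + alpha[f] * A[, , f, 1]
  cam <- pmax(cam, 0)
  degenerate <- max(cam) == 0
  if (!degenerate) cam <- cam / max(cam)
  up <- resize_image(cam, model$arch$input_shape[1], model$arch$input_shape[2])
  up <- clip(up, 0, 1)
  structure(list(values = up, coarse = cam, target_class = target_class,
                 layer = last_conv, degenerate = degenerate),
            class = "heatmap")
}

#' Overlay a heatmap on its source image
#'
#' The heatmap is mapped through a dark-blue-to-red-to-yellow colormap and
#' alpha-blended onto the grayscale rendering of the input:
#' `out = (1 - alpha) * gray + alpha * colormap(heat)`. With `alpha = 0` the
#' (grayscale) input is returned unchanged; a zero heatmap yields a uniformly
#' dimmed input.
#'
#' @param heatmap a [grad_cam()] result (or plain `H x W` matrix in `[0,1]`).
#' @param image the source pixel array (0-255 scale), same spatial size.
#' @param alpha blend weight in `[0, 1]`.
#' @return `H x W x 3` array in 0-255.
#' @export
overlay <- function(heatmap, image, alpha = 0.4) {
  hv <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  gray <- if (length(dim(image)) == 3 && dim(image)[3] == 3)
    luminance(image) else { dim(image) <- dim(image)[1:2]; image }
  if (!all(dim(hv) == dim(gray)))
    stopf("heatmap %s does not match image %s",
          paste(dim(hv), collapse = "x"), paste(dim(gray), collapse = "x"))
  ramp <- grDevices::colorRamp(c("#00002a", "#0000aa", "#aa0000", "#ffff00"))
  rgb <- ramp(as.numeric(clip(hv, 0, 1)))  # n x 3 in 0-255
  out <- array(0, c(dim(gray), 3))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * gray + alpha * matrix(rgb[, ch], nrow(gray))
  clip(out)
}

#' Localization statistic for a heatmap against a ground-truth region
#'
#' @param heatmap a [grad_cam()] result or `H x W` matrix.
#' @param mask logical `H x W` ground-truth feature region.
#' @return list with `inside`, `outside` (mean heatmap values) and `ratio`.
#' @export
heatmap_localization <- function(heatmap, mask) {
  hv <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  if (!all(dim(hv) == dim(mask)))
    mask <- resize_image(mask * 1, nrow(hv), ncol(hv)) > 0.5
  inside <- mean(hv[mask]); outside <- mean(hv[!mask])
  list(inside = inside, outside = outside,
       ratio = if (outside > 0) inside / outside else Inf)
}
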
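#' Domain-filter configuration
#'
#' The domain filter assumes the central frame of a video shows the tympanic
#' membrane / ear canal, histograms it per channel and scores every frame by
#' the Kullback-Leibler divergence from that reference. KL is a dissimilarity,
#' so the threshold is exposed as the maximum allowed divergence: a frame is
#' kept when its score is at most `kl_threshold`.
#'
#' @param kl_threshold nonnegative maximum allowed divergence; frames scoring
#'   above it are discarded. No universal default exists; calibrate with
#'   [calibrate_threshold()] on data with known flags.
#' @param bins histogram bins per channel.
#' @param epsilon smoothing mass added to every bin before normalization so no
#'   bin is empty (KL requires full support).
#' @return object of class `"domain_filter_config"`.
#' @export
domain_filter_config <- function(kl_threshold, bins = 32, epsilon = 1e-8) {
  if (kl_threshold < 0) stopf("kl_threshold must be >= 0")
  if (bins < 2) stopf("bins must be >= 2")
  if (epsilon <= 0) stopf("epsilon must be > 0")
  structure(list(kl_threshold = kl_threshold, bins = as.integer(bins),
                 epsilon = epsilon), class = "domain_filter_config")
}

#' Blur-detector configuration
#'
#' @param variance_threshold nonnegative minimum variance of the Laplacian
#'   response; frames scoring below it are considered uniformly blurred and
#'   discarded.
#' @param channel channel fed to the Laplacian: `"R"`, `"G"`, `"B"` or
#'   `"gray"` (weighted luminance). Default green, the channel with the
#'   highest luminance weight.
#' @return object of class `"blur_config"`.
#' @export
blur_config <- function(variance_threshold, channel = "G") {
  if (variance_threshold < 0) stopf("variance_threshold must be >= 0")
  if (!channel %in% c("R", "G", "B", "gray"))
    stopf("channel must be one of R, G, B, gray")
  structure(list(variance_threshold = variance_threshold, channel = channel),
            class = "blur_config")
}

#' Per-channel smoothed intensity histogram of a frame
#'
#' Pixel intensities (assumed in 0-255) are binned into `bins` equal-width
#' bins per channel; `epsilon` is added to every bin before normalizing so the
#' result has full support and is a valid input to [kl_divergence()].
#'
#' @param frame numeric `H x W x C` (or `H x W`) array.
#' @param bins number of bins, at least 2.
#' @param epsilon smoothing constant added to every bin count.
#' @return object of class `"frame_histogram"`: list with `p` (bins x C matrix
#'   of probabilities, columns summing to 1), `bins`, `channels`.
#' @export
compute_histogram <- function(frame, bins = 32, epsilon = 1e-8) {
  if (length(frame) == 0) stopf("empty frame")
  if (bins < 2) stopf("bins must be >= 2")
  if (is.matrix(frame)) dim(frame) <- c(dim(frame), 1)
  nch <- dim(frame)[3]
  p <- matrix(0, bins, nch)
  breaks <- seq(0, 255, length.out = bins + 1)
  for (ch in seq_len(nch)) {
    v <- clip(as.numeric(frame[, , ch]))
    b <- pmin(pmax(floor(v / 256 * bins) + 1, 1), bins)
    counts <- tabulate(b, nbins = bins) + epsilon
    p[, ch] <- counts / sum(counts)
  }
  structure(list(p = p, bins = as.integer(bins), channels = nch,
                 breaks = breaks), class = "frame_histogram")
}

#' Kullback-Leibler divergence between two frame histograms
#'
#' Computes `D(p || q) = sum p * log(p / q)` (natural log), summed over
#' channels. Nonnegative, and zero exactly when the smoothed histograms are
#' identical.
#'
#' @param p,q [compute_histogram()] results with equal bins and channels.
#' @return scalar divergence.
#' @export
kl_divergence <- function(p, q) {
  if (!inherits(p, "frame_histogram") || !inherits(q, "frame_histogram"))
    stopf("p and q must be frame_histogram objects")
  if (p$bins != q$bins || p$channels != q$channels)
    stopf("histograms disagree: %d bins x %d channels vs %d x %d",
          p$bins, p$channels, q$bins, q$channels)
  sum(p$p * log(p$p / q$p))
}

#' Keep the frames that show the anatomical domain of interest
#'
#' The reference histogram is taken from the central frame (index
#' `floor(n/2) + 1`); every frame is scored by `D(central || frame)` and kept
#' when the score is at most `cfg$kl_threshold`. The central frame is always
#' kept.
#'
#' @param video a `labeled_video` (or an `H x W x 3 x n` frame array).
#' @param cfg a [domain_filter_config()].
#' @return integer vector of kept frame indices (strictly increasing), with
#'   attribute `"scores"` holding every frame's divergence.
#' @export
filter_domain <- function(video, cfg) {
  frames <- if (inherits(video, "labeled_video")) video$frames else video
  n <- dim(frames)[4]
  if (n < 1) stopf("video has no frames")
  central <- n %/% 2 + 1
  ref <- compute_histogram(array(as.numeric(frames[, , , central]),
                                 dim(frames)[1:3]),
                           cfg$bins, cfg$epsilon)
  scores <- vapply(seq_len(n), function(i) {
    h <- compute_histogram(array(as.numeric(frames[, , , i]), dim(frames)[1:3]),
                           cfg$bins, cfg$epsilon)
    kl_divergence(ref, h)
  }, numeric(1))
  kept <- which(scores <= cfg$kl_threshold | seq_len(n) == central)
  structure(kept, scores = scores)
}

#' Sharpness score: variance of the Laplacian response
#'
#' Convolves the selected channel with the 3x3 Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` (reflect padding at the borders) and returns
#' the sample variance of the response. Uniformly blurred images lack the
#' rapid intensity changes the Laplacian highlights, so low scores indicate
#' blur.
#'
#' @param frame numeric `H x W x 3` (or single-plane `H x W`) array.
#' @param channel `"R"`, `"G"`, `"B"` or `"gray"`; ignored for 2-D input.
#' @return nonnegative scalar.
#' @export
laplacian_variance <- function(frame, channel = "G") {
  if (length(frame) == 0) stopf("empty frame")
  x <- if (is.matrix(frame)) frame else switch(channel,
    R = frame[, , 1], G = frame[, , 2], B = frame[, , 3],
    gray = luminance(frame))
  H <- nrow(x); W <- ncol(x)
  up    <- x[c(if (H > 1) 2 else 1, seq_len(H - 1)), , drop = FALSE]
  down  <- x[c(seq_len(H)[-1], if (H > 1) H - 1 else 1), , drop = FALSE]
  left  <- x[, c(if (W > 1) 2 else 1, seq_len(W - 1)), drop = FALSE]
  right <- x[, c(seq_len(W)[-1], if (W > 1) W - 1 else 1), drop = FALSE]
  lap <- up + down + left + right - 4 * x
  v <- var(as.numeric(lap))
  if (is.na(v)) 0 else v
}

#' Keep the sharp frames among a set of candidates
#'
#' @param video a `labeled_video` or `H x W x 3 x n` array.
#' @param indices candidate frame indices (typically the [filter_domain()]
#'   output); defaults to all frames.
#' @param cfg a [blur_config()]; frames with Laplacian variance at least
#'   `cfg$variance_threshold` are kept.
#' @return integer subset of `indices`, in the same (increasing) order, with
#'   attribute `"scores"` holding each candidate's blur score.
#' @export
filter_blur <- function(video, indices = NULL, cfg) {
  frames <- if (inherits(video, "labeled_video")) video$frames else video
  n <- dim(frames)[4]
  if (is.null(indices)) indices <- seq_len(n)
  if (any(indices < 1 | indices > n)) stopf("frame index out of range")
  scores <- vapply(indices, function(i)
    laplacian_variance(array(as.numeric(frames[, , , i]), dim(frames)[1:3]),
                       cfg$channel), numeric(1))
  kept <- indices[scores >= cfg$variance_threshold]
  structure(kept, scores = scores)
}

#' Calibrate a filter threshold from scored frames with known ground truth
#'
#' Sweeps a threshold between the two score populations and returns the
#' midpoint between the population boundaries, together with the achieved
#' agreement. For `direction = "keep_below"` (domain filter: keep scores <=
#' threshold) the ideal threshold lies between `max(scores[keep])` and
#' `min(scores[discard])`; for `"keep_above"` (blur filter) between
#' `max(scores[discard])` and `min(scores[keep])`.
#'
#' @param scores numeric frame scores.
#' @param keep_truth logical ground truth: should the frame be kept?
#' @param direction `"keep_below"` or `"keep_above"`.
#' @return list with `threshold`, `agreement` (fraction of frames the
#'   thresholded rule classifies like the truth) and `separable` (TRUE when
#'   agreement is exactly 1).
#' @export
calibrate_threshold <- function(scores, keep_truth,
                                direction = c("keep_below", "keep_above")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(keep_truth))
  if (all(keep_truth) || !any(keep_truth)) {
    thr <- if (all(keep_truth) == (direction == "keep_below"))
      max(scores) else min(scores)
    return(list(threshold = thr, agreement = 1, separable = TRUE))
  }
  a <- scores[keep_truth]; b <- scores[!keep_truth]
  if (direction == "keep_below") {
    thr <- (max(a) + min(b)) / 2
    pred <- scores <= thr
  } else {
    thr <- (max(b) + min(a)) / 2
    pred <- scores >= thr
  }
  agreement <- mean(pred == keep_truth)
  list(threshold = thr, agreement = agreement, separable = agreement == 1)
}
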
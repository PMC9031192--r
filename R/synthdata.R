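#' Specification for the synthetic otoscopy-video generator
#'
#' Describes a seeded synthetic dataset of otoscopy videos with four ear
#' conditions whose discriminative feature is injected predominantly into one
#' color channel, plus the acquisition artifacts the preprocessing stages must
#' remove (out-of-domain lead-in/lead-out frames, intermittently blurred
#' frames).
#'
#' Each video shows a circular "ear canal" scene containing an eardrum disc.
#' Class features are parametric geometric primitives: radial vascular streaks
#' (chronic otitis media), a lower-half fluid fill (otitis media with
#' effusion), a central occluding blob (earwax plug), and a clean disc
#' (normal). A feature pixel is brightened by `base_contrast` in all three
#' channels (so the feature is visible, chromatically neutral) and by an
#' additional `signal_strength` in `signal_channel` only, which localizes the
#' class-discriminative contrast in that channel.
#'
#' @param n_videos_per_class videos generated per class.
#' @param frames_per_video frames per video; must exceed `2 * lead_frames`.
#' @param frame_shape integer vector `c(height, width, 3)` in pixels.
#'   Default 480 x 640, the resolution of a consumer digital otoscope.
#' @param classes ordered character vector of the four class names.
#' @param signal_channel `"R"`, `"G"` or `"B"`: channel carrying the boosted
#'   class contrast.
#' @param signal_strength intensity offset in `[0, 255]` added to feature
#'   pixels in `signal_channel`.
#' @param base_contrast chromatically neutral intensity offset added to
#'   feature pixels in all channels.
#' @param lead_frames out-of-domain frames at the start AND at the end of each
#'   video (the recording runs before insertion and after removal of the
#'   otoscope specula).
#' @param blur_fraction fraction in `[0, 1]` of in-domain frames that are
#'   Gaussian-blurred (camera movement / out-of-focus).
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param noise_sigma additive Gaussian pixel-noise standard deviation.
#' @param fps nominal frame rate, frames per second.
#' @param seed master integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `"synthetic_spec"`.
#' @seealso [generate_video()], [generate_dataset()]
#' @export
synthetic_spec <- function(n_videos_per_class = 50,
                           frames_per_video = 200,
                           frame_shape = c(480, 640, 3),
                           classes = c("normal", "com", "ome", "earwax"),
                           signal_channel = "G",
                           signal_strength = 40,
                           base_contrast = 15,
                           lead_frames = 20,
                           blur_fraction = 0.2,
                           blur_sigma = 3,
                           noise_sigma = 8,
                           fps = 20,
                           seed = 1L) {
  if (length(frame_shape) != 3 || frame_shape[3] != 3)
    stopf("frame_shape must be c(height, width, 3)")
  if (frames_per_video <= 2 * lead_frames)
    stopf("frames_per_video (%d) must exceed 2 * lead_frames (%d)",
          frames_per_video, 2 * lead_frames)
  if (blur_fraction < 0 || blur_fraction > 1)
    stopf("blur_fraction must lie in [0, 1]")
  if (signal_strength < 0) stopf("signal_strength must be >= 0")
  if (!signal_channel %in% c("R", "G", "B"))
    stopf("signal_channel must be one of R, G, B")
  if (length(classes) != 4) stopf("exactly four classes are required")
  structure(list(
    n_videos_per_class = as.integer(n_videos_per_class),
    frames_per_video = as.integer(frames_per_video),
    frame_shape = as.integer(frame_shape),
    classes = classes,
    signal_channel = signal_channel,
    signal_strength = signal_strength,
    base_contrast = base_contrast,
    lead_frames = as.integer(lead_frames),
    blur_fraction = blur_fraction,
    blur_sigma = blur_sigma,
    noise_sigma = noise_sigma,
    fps = fps,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Per-video scene parameters (feature geometry) drawn once per video.
draw_scene_params <- function(spec, class_label) {
  H <- spec$frame_shape[1]; W <- spec$frame_shape[2]
  r <- 0.38 * min(H, W)
  list(
    cy = H / 2 + runif(1, -0.03, 0.03) * H,
    cx = W / 2 + runif(1, -0.03, 0.03) * W,
    r = r,
    n_streaks = sample(7:10, 1),
    streak_phase = runif(1, 0, 2 * pi),
    fluid_level = runif(1, -0.15, 0.15),       # fraction of r below center
    plug_r = r * runif(1, 0.40, 0.50),
    plug_dy = runif(1, -0.1, 0.1) * r,
    plug_dx = runif(1, -0.1, 0.1) * r
  )
}

# Logical feature mask for a class at center (cy, cx); H x W.
feature_mask_for <- function(class_idx, H, W, p, cy, cx) {
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- row - cy; dx <- col - cx
  d <- sqrt(dy^2 + dx^2)
  inside <- d < p$r
  switch(class_idx,
    matrix(FALSE, H, W),                                        # normal
    inside & d > 0.15 * p$r &                                   # COM streaks
      sin(p$n_streaks * atan2(dy, dx) + p$streak_phase) > 0.75,
    inside & dy > p$fluid_level * p$r,                          # OME fluid
    sqrt((dy - p$plug_dy)^2 + (dx - p$plug_dx)^2) < p$plug_r    # earwax plug
  )
}

# Render one in-domain frame (float H x W x 3, un-noised).
render_frame <- function(spec, class_idx, p, jy, jx) {
  H <- spec$frame_shape[1]; W <- spec$frame_shape[2]
  cy <- p$cy + jy; cx <- p$cx + jx
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((row - cy)^2 + (col - cx)^2)
  inside <- d < p$r
  base <- ifelse(inside, 130 - 70 * (d / p$r)^2, 25)
  mask <- feature_mask_for(class_idx, H, W, p, cy, cx)
  sig_idx <- match(spec$signal_channel, c("R", "G", "B"))
  frame <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    boost <- spec$base_contrast + if (ch == sig_idx) spec$signal_strength else 0
    frame[, , ch] <- base + mask * boost
  }
  frame
}

# Render one out-of-domain frame: a bright low-frequency noise field with an
# intensity histogram far from the in-domain scene's, so the domain filter is
# testable by construction.
render_out_of_domain <- function(spec) {
  H <- spec$frame_shape[1]; W <- spec$frame_shape[2]
  frame <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    coarse <- matrix(runif(6 * 8), 6, 8)
    frame[, , ch] <- 200 + 30 * resize_image(coarse, H, W)
  }
  frame
}

#' Generate one synthetic labeled otoscopy video
#'
#' Central frames contain the circular eardrum scene with the class-specific
#' feature; the first and last `lead_frames` frames are out-of-domain fields
#' drawn from a shifted intensity distribution; a `blur_fraction` share of
#' in-domain frames is Gaussian-blurred. Ground truth is recorded per frame.
#'
#' @param spec a [synthetic_spec()].
#' @param class_label one of `spec$classes`.
#' @param video_seed integer seed for this video.
#' @return object of class `"labeled_video"`: list with `frames` (integer
#'   `H x W x 3 x n` array, values 0-255), `label`, `flags` (data.frame with
#'   `is_in_domain`, `is_blurred`), `fps`, `feature_mask` (H x W logical,
#'   nominal-center class-feature region) and `seed`.
#' @export
generate_video <- function(spec, class_label, video_seed) {
  ci <- match(class_label, spec$classes)
  if (is.na(ci))
    stopf("unknown class '%s'; valid classes: %s", class_label,
          paste(spec$classes, collapse = ", "))
  H <- spec$frame_shape[1]; W <- spec$frame_shape[2]
  n <- spec$frames_per_video; lead <- spec$lead_frames
  with_seed(video_seed, {
    p <- draw_scene_params(spec, class_label)
    in_domain <- rep(TRUE, n)
    if (lead > 0) in_domain[c(seq_len(lead), n - seq_len(lead) + 1)] <- FALSE
    idx_in <- which(in_domain)
    blurred <- rep(FALSE, n)
    n_blur <- round(spec$blur_fraction * length(idx_in))
    if (n_blur > 0) blurred[sample(idx_in, n_blur)] <- TRUE
    frames <- array(0L, c(H, W, 3, n))
    for (i in seq_len(n)) {
      if (in_domain[i]) {
        jy <- rnorm(1, 0, 0.01 * H); jx <- rnorm(1, 0, 0.01 * W)  # camera shake
        f <- render_frame(spec, ci, p, jy, jx)
      } else {
        f <- render_out_of_domain(spec)
      }
      f <- f + array(rnorm(H * W * 3, 0, spec$noise_sigma), c(H, W, 3))
      if (blurred[i]) f <- as.array(EBImage::gblur(f, sigma = spec$blur_sigma))
      frames[, , , i] <- as.integer(round(clip(f)))
    }
    structure(list(
      frames = frames,
      label = class_label,
      flags = data.frame(is_in_domain = in_domain, is_blurred = blurred),
      fps = spec$fps,
      feature_mask = feature_mask_for(ci, H, W, p, p$cy, p$cx),
      seed = as.integer(video_seed)
    ), class = "labeled_video")
  })
}

#' @export
print.labeled_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<labeled_video> %s: %d frames %dx%dx%d @ %g fps (%d in-domain, %d blurred)\n",
              x$label, d[4], d[1], d[2], d[3], x$fps,
              sum(x$flags$is_in_domain), sum(x$flags$is_blurred)))
  invisible(x)
}

#' Generate a balanced synthetic video dataset
#'
#' Produces `n_videos_per_class` videos per class. Per-video seeds are derived
#' deterministically from `spec$seed`, the class index and the video index, so
#' the dataset is reproducible without global RNG state.
#'
#' @param spec a [synthetic_spec()].
#' @return list of [generate_video()] results, class-major order.
#' @export
generate_dataset <- function(spec) {
  out <- vector("list", length(spec$classes) * spec$n_videos_per_class)
  k <- 0
  for (ci in seq_along(spec$classes)) {
    for (vi in seq_len(spec$n_videos_per_class)) {
      k <- k + 1
      out[[k]] <- generate_video(spec, spec$classes[ci],
                                 derive_seed(spec$seed, ci, vi))
    }
  }
  out
}

#' Extract one frame of a video as a float array
#'
#' @param video a `labeled_video`.
#' @param i frame index.
#' @return numeric `H x W x 3` array, values in 0-255.
#' @export
video_frame <- function(video, i) {
  f <- video$frames[, , , i, drop = FALSE]
  array(as.numeric(f), dim(f)[1:3])
}

#' Write a video as a directory of PNG frames
#'
#' Frames are written as `frame_%05d.png` plus a `flags.csv` with the
#' per-frame ground-truth provenance flags.
#'
#' @param video a `labeled_video`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_video_frames <- function(video, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(video$frames)[4]
  for (i in seq_len(n)) {
    f <- video_frame(video, i) / 255
    png::writePNG(f, file.path(dir, sprintf("frame_%05d.png", i)))
  }
  write.csv(cbind(frame = seq_len(n), video$flags),
            file.path(dir, "flags.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a video dataset to disk with a manifest
#'
#' @param videos list of `labeled_video` objects.
#' @param dir output root; one subdirectory per video plus `manifest.csv`
#'   (path, class, seed).
#' @return path of the manifest, invisibly.
#' @export
write_dataset <- function(videos, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(videos), function(i) {
    v <- videos[[i]]
    sub <- sprintf("video_%03d_%s", i, v$label)
    write_video_frames(v, file.path(dir, sub))
    data.frame(path = sub, class = v$label, seed = v$seed)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
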
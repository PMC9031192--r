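# Shared fixtures, memoized so expensive objects (videos, trained models,
# the scaled-down study) are built once per test run.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- expr
  .fx[[name]]
}

# Small-frame generator spec used throughout the tests (96x128 frames).
fx_spec <- function(seed = 11, ...) {
  args <- list(n_videos_per_class = 3, frames_per_video = 40,
               frame_shape = c(96, 128, 3), lead_frames = 6,
               blur_fraction = 0.15, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

fx_video <- function() memo("video", generate_video(fx_spec(), "com", 42))

# A long single video with > 100 usable frames for the keyframe contract.
fx_long_video <- function() memo("long_video", {
  generate_video(fx_spec(frames_per_video = 140, lead_frames = 10,
                         blur_fraction = 0.1, seed = 3), "ome", 99)
})

# Balanced labeled image set drawn from in-domain sharp frames (no training).
fx_images <- function() memo("images", {
  vids <- generate_dataset(fx_spec(n_videos_per_class = 1, seed = 21))
  images <- list(); labels <- character(0)
  for (v in vids) {
    idx <- which(v$flags$is_in_domain & !v$flags$is_blurred)
    for (i in idx) images <- c(images, list(video_frame(v, i)))
    labels <- c(labels, rep(v$label, length(idx)))
  }
  list(images = images, labels = labels)
})

# Scaled-down three-mode study: green-signal generator, gray_g / gray_r /
# gray_b tiny models, 3 trials, Grad-CAM samples. Backs the channel-recovery
# and Grad-CAM acceptance checks.
fx_study <- function() memo("study", {
  cfg <- study_config(
    spec = fx_spec(seed = 11),
    kf_cfg = keyframe_config(n_components = 10, k = 20, downsample = 32,
                             seed = 1),
    modes = c("gray_g", "gray_r", "gray_b"),
    train_cfg = train_config(learning_rate = 1e-3, batch_size = 16,
                             epochs = 20, n_trials = 3, seed = 1),
    test_n = 15, gradcam_n = 20, seed = 11)
  suppressWarnings(run_study(cfg))
})

# A quickly trained tiny model on gray_g images (for Grad-CAM unit tests).
fx_trained_tiny <- function() memo("trained_tiny", {
  d <- fx_images()
  ds <- batch_spectral(d$images, d$labels, "gray_g")
  cfg <- train_config(learning_rate = 1e-3, batch_size = 16, epochs = 10,
                      n_trials = 1, seed = 5)
  suppressWarnings(train(build_tiny(), ds$images, ds$labels, cfg,
                         classes = fx_spec()$classes, mode = "gray_g"))
})

# Random valid confusion matrix (counts), c classes.
random_cm <- function(c_n = 4, n = 200) {
  m <- matrix(0L, c_n, c_n,
              dimnames = list(truth = paste0("c", seq_len(c_n)),
                              predicted = paste0("c", seq_len(c_n))))
  t_i <- sample.int(c_n, n, replace = TRUE)
  p_i <- sample.int(c_n, n, replace = TRUE)
  for (k in seq_len(n)) m[t_i[k], p_i[k]] <- m[t_i[k], p_i[k]] + 1L
  m
}
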
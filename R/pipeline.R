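#' Study configuration
#'
#' One object driving the whole color-dependence study: data source, frame
#' filters, keyframe summarization, spectral modes, architecture, training
#' protocol and split sizes.
#'
#' @param spec a [synthetic_spec()] (data generated on the fly) or NULL when
#'   `input_dir` is given.
#' @param input_dir directory previously written by [write_dataset()].
#' @param domain_cfg a [domain_filter_config()], or NULL to calibrate the KL
#'   threshold against the generator's ground-truth flags (synthetic source
#'   only).
#' @param blur_cfg a [blur_config()], or NULL to calibrate likewise.
#' @param kf_cfg a [keyframe_config()].
#' @param modes subset of [channel_modes()] to train; default all seven.
#' @param arch `"tiny"` or `"vgg16"`; the desk-scale default is tiny.
#' @param train_cfg a [train_config()].
#' @param test_n test samples per class (the clinical protocol used 500).
#' @param gradcam_n Grad-CAM sample images drawn from the test set.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param seed master seed; every stage derives its own seed from it.
#' @return object of class `"study_config"`.
#' @export
study_config <- function(spec = synthetic_spec(), input_dir = NULL,
                         domain_cfg = NULL, blur_cfg = NULL,
                         kf_cfg = keyframe_config(),
                         modes = channel_modes(), arch = c("tiny", "vgg16"),
                         train_cfg = train_config(), test_n = 500,
                         gradcam_n = 0, out_dir = NULL, seed = 1L) {
  arch <- match.arg(arch)
  bad <- setdiff(modes, channel_modes())
  if (length(bad)) stopf("unknown mode(s): %s", paste(bad, collapse = ", "))
  structure(list(spec = spec, input_dir = input_dir, domain_cfg = domain_cfg,
                 blur_cfg = blur_cfg, kf_cfg = kf_cfg, modes = modes,
                 arch = arch, train_cfg = train_cfg,
                 test_n = as.integer(test_n), gradcam_n = as.integer(gradcam_n),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

#' Stratified train/validation/test split at the image level
#'
#' Each class contributes exactly `test_n` test images; the remainder is
#' split `train_frac` / `1 - train_frac` into training and validation. The
#' three sets are disjoint and together cover all indices. With the clinical
#' protocol's numbers (5,500 per class, 500 test, 80/20) this yields
#' 4,000 / 1,000 / 500 per class.
#'
#' @param labels class label per image.
#' @param test_n test images per class.
#' @param train_frac training fraction of the non-test remainder.
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, test_n, train_frac = 0.8, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts <= test_n))
    stopf("insufficient samples: need > %d per class, have [%s]",
          test_n, paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  with_seed(seed, {
    train <- integer(0); val <- integer(0); test <- integer(0)
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      test <- c(test, idx[seq_len(test_n)])
      rest <- idx[-seq_len(test_n)]
      n_tr <- round(train_frac * length(rest))
      train <- c(train, rest[seq_len(n_tr)])
      val <- c(val, rest[-seq_len(n_tr)])
    }
    sets <- list(train = sort(train), val = sort(val), test = sort(test))
    overlap <- c(intersect(sets$train, sets$val),
                 intersect(sets$train, sets$test),
                 intersect(sets$val, sets$test))
    stopifnot(length(overlap) == 0)  # leakage check, asserted every run
    sets
  })
}

#' Read a video dataset written by [write_dataset()]
#'
#' @param dir dataset root containing `manifest.csv`.
#' @return list of `labeled_video` objects (without feature masks).
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    vdir <- file.path(dir, manifest$path[i])
    files <- sort(list.files(vdir, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    frames_l <- lapply(files, function(f) png::readPNG(f) * 255)
    d <- dim(frames_l[[1]])
    frames <- array(0L, c(d, length(frames_l)))
    for (k in seq_along(frames_l))
      frames[, , , k] <- as.integer(round(frames_l[[k]]))
    flags_path <- file.path(vdir, "flags.csv")
    flags <- if (file.exists(flags_path))
      read.csv(flags_path)[c("is_in_domain", "is_blurred")]
    else data.frame(is_in_domain = rep(NA, length(files)),
                    is_blurred = rep(NA, length(files)))
    structure(list(frames = frames, label = manifest$class[i], flags = flags,
                   fps = NA_real_, feature_mask = NULL,
                   seed = manifest$seed[i]), class = "labeled_video")
  })
}

# Calibrate filter thresholds against the generator's ground-truth flags.
calibrate_filters <- function(videos, bins = 32, epsilon = 1e-8,
                              blur_channel = "G") {
  dom_scores <- numeric(0); dom_truth <- logical(0)
  blur_scores <- numeric(0); blur_truth <- logical(0)
  probe_dom <- domain_filter_config(Inf, bins, epsilon)
  probe_blur <- blur_config(0, blur_channel)
  for (v in videos) {
    kd <- filter_domain(v, probe_dom)
    dom_scores <- c(dom_scores, attr(kd, "scores"))
    dom_truth <- c(dom_truth, v$flags$is_in_domain)
    idx <- which(v$flags$is_in_domain)
    kb <- filter_blur(v, idx, probe_blur)
    blur_scores <- c(blur_scores, attr(kb, "scores"))
    blur_truth <- c(blur_truth, !v$flags$is_blurred[idx])
  }
  dom <- calibrate_threshold(dom_scores, dom_truth, "keep_below")
  blr <- calibrate_threshold(blur_scores, blur_truth, "keep_above")
  list(domain_cfg = domain_filter_config(dom$threshold, bins, epsilon),
       blur_cfg = blur_config(blr$threshold, blur_channel),
       domain_agreement = dom$agreement, blur_agreement = blr$agreement)
}

# Average a list of metrics_report objects (mean of macro vector and of the
# per-class table, element-wise over trials).
average_reports <- function(reports) {
  macro <- rowMeans(vapply(reports, `[[`, numeric(5), "macro"))
  pc <- reports[[1]]$per_class
  for (col in names(pc)[-1])
    pc[[col]] <- rowMeans(vapply(reports, function(r) r$per_class[[col]],
                                 numeric(nrow(pc))))
  structure(list(macro = macro, per_class = pc,
                 n_classes = reports[[1]]$n_classes,
                 n_trials = length(reports)),
            class = "metrics_report")
}

#' Run the full color-dependence study
#'
#' Executes every stage from one config: data generation (or ingestion),
#' domain and blur filtering (calibrated against generator flags when no
#' thresholds are given), keyframe summarization, per-class balancing,
#' stratified image-level splitting, per-mode spectral conversion and
#' training over `n_trials` trials, test-set evaluation, cross-mode
#' comparison and optional Grad-CAM localization samples. All randomness is
#' derived from `cfg$seed`; the returned manifest suffices to reproduce any
#' stage.
#'
#' @param cfg a [study_config()].
#' @return list with `reports` (per-mode trial-averaged metrics), `per_trial`
#'   (per-mode list of per-trial reports), `comparison` (cross-mode table),
#'   `models` (last-trial model per mode), `split`, `labels`, `gradcam`
#'   (localization stats, when requested) and `manifest`.
#' @export
run_study <- function(cfg) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("study stage '%s' failed: %s", name, conditionMessage(e)))
  }
  videos <- stage("data", {
    if (!is.null(cfg$input_dir)) read_dataset(cfg$input_dir)
    else generate_dataset(cfg$spec)
  })
  classes <- if (!is.null(cfg$spec)) cfg$spec$classes
             else unique(vapply(videos, `[[`, "", "label"))

  cal <- NULL
  if (is.null(cfg$domain_cfg) || is.null(cfg$blur_cfg)) {
    cal <- stage("calibrate", calibrate_filters(videos))
    if (is.null(cfg$domain_cfg)) cfg$domain_cfg <- cal$domain_cfg
    if (is.null(cfg$blur_cfg)) cfg$blur_cfg <- cal$blur_cfg
  }

  pooled <- stage("keyframes", {
    images <- list(); labels <- character(0); masks <- list()
    for (v in videos) {
      s <- summarize_video(v, cfg$domain_cfg, cfg$blur_cfg, cfg$kf_cfg)
      images <- c(images, s$keyframes)
      labels <- c(labels, rep(v$label, length(s$keyframes)))
      masks <- c(masks, rep(list(v$feature_mask), length(s$keyframes)))
    }
    list(images = images, labels = labels, masks = masks)
  })

  # balance per-class image counts exactly (keyframing already caps per video)
  balanced <- stage("balance", {
    keep <- integer(0)
    n_min <- min(table(pooled$labels))
    for (cl in classes) keep <- c(keep, which(pooled$labels == cl)[seq_len(n_min)])
    keep <- sort(keep)
    list(images = pooled$images[keep], labels = pooled$labels[keep],
         masks = pooled$masks[keep])
  })

  split <- stage("split", split_dataset(balanced$labels, cfg$test_n,
                                        1 - cfg$train_cfg$val_fraction,
                                        derive_seed(cfg$seed, 101)))

  reports <- list(); per_trial <- list(); models <- list()
  for (mi in seq_along(cfg$modes)) {
    mode <- cfg$modes[mi]
    ds <- stage(paste0("spectral:", mode),
                batch_spectral(balanced$images, balanced$labels, mode))
    trial_reports <- list()
    model <- NULL
    for (tr in seq_len(cfg$train_cfg$n_trials)) {
      tcfg <- cfg$train_cfg
      tcfg$seed <- derive_seed(cfg$seed, 1000 + mi, tr)
      model <- stage(paste0("train:", mode), {
        m <- if (cfg$arch == "tiny")
          build_tiny(n_classes = length(classes),
                     input_shape = c(32, 32, mode_channels(mode)))
        else build_vgg16(n_classes = length(classes),
                         input_shape = c(224, 224, mode_channels(mode)))
        train(m, ds$images[split$train], ds$labels[split$train], tcfg,
              classes = classes, mode = mode,
              val_images = ds$images[split$val],
              val_labels = ds$labels[split$val])
      })
      trial_reports[[tr]] <- stage(paste0("evaluate:", mode),
        evaluate_model(model, ds$images[split$test],
                       ds$labels[split$test])$metrics)
    }
    per_trial[[mode]] <- trial_reports
    reports[[mode]] <- average_reports(trial_reports)
    models[[mode]] <- model
  }

  comparison <- if (length(reports) >= 2) compare_models(reports) else NULL

  gradcam_stats <- NULL
  if (cfg$gradcam_n > 0) {
    gradcam_stats <- stage("gradcam", {
      m <- models[[1]]
      cand <- split$test[balanced$labels[split$test] != classes[1] &
                         !vapply(balanced$masks[split$test], is.null, TRUE)]
      cand <- head(cand, cfg$gradcam_n)
      ds1 <- batch_spectral(balanced$images[cand], balanced$labels[cand],
                            cfg$modes[1])
      do.call(rbind, lapply(seq_along(cand), function(k) {
        hm <- grad_cam(m, ds1$images[[k]], ds1$labels[k])
        loc <- heatmap_localization(hm, balanced$masks[[cand[k]]])
        data.frame(index = cand[k], class = ds1$labels[k],
                   inside = loc$inside, outside = loc$outside)
      }))
    })
  }

  manifest <- list(
    seed = cfg$seed, arch = cfg$arch, modes = cfg$modes,
    n_videos = length(videos), n_images = length(balanced$images),
    images_per_class = unname(min(table(balanced$labels))),
    split_sizes = vapply(split, length, 0L),
    kl_threshold = cfg$domain_cfg$kl_threshold,
    variance_threshold = cfg$blur_cfg$variance_threshold,
    calibration = if (!is.null(cal))
      list(domain_agreement = cal$domain_agreement,
           blur_agreement = cal$blur_agreement) else NULL,
    n_trials = cfg$train_cfg$n_trials,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  bundle <- list(reports = reports, per_trial = per_trial,
                 comparison = comparison, models = models, split = split,
                 labels = balanced$labels, gradcam = gradcam_stats,
                 manifest = manifest)
  if (!is.null(cfg$out_dir)) write_study(bundle, cfg$out_dir)
  bundle
}

# Serialize the tabular study outputs (CSV; manifest as JSON when jsonlite is
# available).
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$comparison))
    write.csv(bundle$comparison, file.path(dir, "comparison.csv"),
              row.names = FALSE)
  for (mode in names(bundle$reports)) {
    r <- bundle$reports[[mode]]
    write.csv(cbind(metric = names(r$macro),
                    value = unname(r$macro)),
              file.path(dir, sprintf("metrics_%s.csv", mode)),
              row.names = FALSE)
    write.csv(r$per_class,
              file.path(dir, sprintf("metrics_%s_per_class.csv", mode)),
              row.names = FALSE)
  }
  if (!is.null(bundle$gradcam))
    write.csv(bundle$gradcam, file.path(dir, "gradcam.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
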
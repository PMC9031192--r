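#' Keyframe-selection configuration
#'
#' Video summarization embeds every usable frame with PCA and picks one
#' representative frame per k-means cluster, yielding `k` keyframes. The
#' default of 20 components reflects that, on otoscopy footage, the leading
#' 20 components explain about 80% of the frame variance; `variance_target`
#' offers the explained-variance rule directly as an alternative.
#'
#' @param n_components number of principal components retained.
#' @param k number of clusters = number of keyframes. Default 100, the
#'   per-video summary size used to balance the study database.
#' @param variance_target optional fraction in (0, 1]; when set, the smallest
#'   number of components whose cumulative explained variance reaches it is
#'   used instead of `n_components`.
#' @param downsample side length frames are downsampled to (after grayscale
#'   conversion) before flattening for PCA.
#' @param seed integer seed for k-means.
#' @return object of class `"keyframe_config"`.
#' @export
keyframe_config <- function(n_components = 20, k = 100, variance_target = NULL,
                            downsample = 64, seed = 1L) {
  if (n_components < 1) stopf("n_components must be >= 1")
  if (k < 1) stopf("k must be >= 1")
  if (!is.null(variance_target) &&
      (variance_target <= 0 || variance_target > 1))
    stopf("variance_target must lie in (0, 1]")
  structure(list(n_components = as.integer(n_components), k = as.integer(k),
                 variance_target = variance_target,
                 downsample = as.integer(downsample), seed = as.integer(seed)),
            class = "keyframe_config")
}

#' PCA embedding of video frames
#'
#' Frames are converted to weighted-luminance grayscale, downsampled to
#' `cfg$downsample` square, flattened, mean-centered and projected onto the
#' leading principal components (either `cfg$n_components` or, when
#' `cfg$variance_target` is set, the fewest components reaching that
#' cumulative explained-variance fraction).
#'
#' @param frames list of `H x W x 3` arrays (or a single `H x W x 3 x n`
#'   array).
#' @param cfg a [keyframe_config()].
#' @return list with `embeddings` (n x m matrix), `explained` (non-increasing
#'   explained-variance fractions of ALL computed components, summing to <= 1)
#'   and `n_used` (components retained).
#' @export
fit_frame_pca <- function(frames, cfg = keyframe_config()) {
  frames <- as_frame_list(frames)
  n <- length(frames)
  if (n < 2) stopf("PCA needs at least 2 frames, got %d", n)
  s <- cfg$downsample
  X <- t(vapply(frames, function(f) {
    g <- if (length(dim(f)) == 3) luminance(f) else f
    as.numeric(resize_image(g, s, s))
  }, numeric(s * s)))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  m <- if (!is.null(cfg$variance_target)) {
    max(1, which(cumsum(explained) >= cfg$variance_target)[1])
  } else min(cfg$n_components, ncol(pc$x))
  if (is.na(m)) m <- ncol(pc$x)
  list(embeddings = pc$x[, seq_len(m), drop = FALSE],
       explained = explained, n_used = m)
}

# k-means++ seeding: first center uniform, later centers drawn with
# probability proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2)
      d2 <- pmin(d2, rowSums((X - matrix(X[centers[j], ], n, ncol(X),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

# Seeded k-means with k-means++ initialization and `restarts` restarts;
# returns the stats::kmeans fit with the lowest total within-cluster SS.
kmeans_pp <- function(X, k, seed, restarts = 10) {
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- X[kmeanspp_centers(X, k), , drop = FALSE]
      fit <- suppressWarnings(
        kmeans(X, centers = init, iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
}

#' Select keyframes by k-means in PCA space
#'
#' Partitions the frame embeddings into `cfg$k` clusters (k-means++
#' initialization, 10 restarts, seeded) and selects from each cluster the
#' single frame with the smallest Euclidean distance to its centroid; ties
#' break to the lowest original frame index. If there are at most `cfg$k`
#' frames, all frames are returned.
#'
#' @param embeddings n x m matrix from [fit_frame_pca()].
#' @param cfg a [keyframe_config()].
#' @param frame_indices original frame indices the embedding rows correspond
#'   to (default `1:n`); selected indices are reported in this space.
#' @return object of class `"keyframe_set"`: list with `indices` (ascending
#'   original frame indices), `cluster_assignments` (per embedding row) and
#'   `embeddings`.
#' @export
select_keyframes <- function(embeddings, cfg = keyframe_config(),
                             frame_indices = seq_len(nrow(embeddings))) {
  if (cfg$k < 1) stopf("k must be >= 1")
  n <- nrow(embeddings)
  stopifnot(length(frame_indices) == n)
  if (n <= cfg$k) {
    return(structure(list(indices = sort(frame_indices),
                          cluster_assignments = seq_len(n),
                          embeddings = embeddings), class = "keyframe_set"))
  }
  fit <- kmeans_pp(embeddings, cfg$k, cfg$seed)
  dist_to_centroid <- sqrt(rowSums(
    (embeddings - fit$centers[fit$cluster, , drop = FALSE])^2))
  chosen <- integer(0)
  for (cl in sort(unique(fit$cluster))) {
    members <- which(fit$cluster == cl)
    chosen <- c(chosen,
                members[which.min(dist_to_centroid[members])])  # first = lowest index
  }
  # Degenerate case: an empty cluster leaves fewer than k representatives;
  # top up with the frames farthest from their assigned centroid (the points
  # an extra cluster seed would capture).
  while (length(chosen) < cfg$k) {
    pool <- setdiff(seq_len(n), chosen)
    chosen <- c(chosen, pool[which.max(dist_to_centroid[pool])])
  }
  structure(list(indices = sort(frame_indices[chosen]),
                 cluster_assignments = fit$cluster,
                 embeddings = embeddings), class = "keyframe_set")
}

#' Summarize a video into keyframes
#'
#' Convenience composition: domain filter, blur filter, PCA embedding,
#' k-means keyframe selection.
#'
#' @param video a `labeled_video`.
#' @param domain_cfg a [domain_filter_config()].
#' @param blur_cfg a [blur_config()].
#' @param kf_cfg a [keyframe_config()].
#' @return list with `keyframes` (list of `H x W x 3` float arrays), `indices`
#'   (original frame indices), `label`.
#' @export
summarize_video <- function(video, domain_cfg, blur_cfg, kf_cfg) {
  kept <- filter_domain(video, domain_cfg)
  kept <- filter_blur(video, kept, blur_cfg)
  frames <- lapply(kept, function(i) video_frame(video, i))
  if (length(frames) < 2) {
    return(list(keyframes = frames, indices = as.integer(kept),
                label = video$label))
  }
  emb <- fit_frame_pca(frames, kf_cfg)
  ks <- select_keyframes(emb$embeddings, kf_cfg, frame_indices = kept)
  sel <- match(ks$indices, kept)
  list(keyframes = frames[sel], indices = ks$indices, label = video$label)
}

# Normalize frame input to a list of arrays.
as_frame_list <- function(frames) {
  if (is.list(frames)) return(frames)
  if (is.array(frames) && length(dim(frames)) == 4)
    return(lapply(seq_len(dim(frames)[4]), function(i)
      array(as.numeric(frames[, , , i]), dim(frames)[1:3])))
  stopf("frames must be a list of arrays or an H x W x C x n array")
}
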
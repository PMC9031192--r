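test_that("frame PCA reports sane explained variance", {
  # frames on a 1-D intensity ramp: first component explains ~100%
  ramp <- lapply(seq(0, 200, length.out = 10), function(v)
    array(v + 5 * outer(1:16, 1:16, "+") / 32, c(16, 16, 3)))
  fit <- fit_frame_pca(ramp, keyframe_config(n_components = 3, downsample = 16))
  expect_gt(fit$explained[1], 0.999)
  expect_true(all(diff(fit$explained) <= 1e-12))
  expect_lte(sum(fit$explained), 1 + 1e-9)
  expect_error(fit_frame_pca(ramp[1], keyframe_config()), "at least 2")
})

test_that("retained variance equals total minus reconstruction error", {
  # eigendecomposition oracle on a 10-frame toy video
  set.seed(3)
  frames <- lapply(1:10, function(i)
    matrix(runif(64, 0, 255), 8, 8))
  cfg <- keyframe_config(n_components = 4, downsample = 8)
  fit <- fit_frame_pca(frames, cfg)
  X <- t(sapply(frames, as.numeric))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  total_var <- sum(diag(crossprod(Xc) / (nrow(X) - 1)))
  # explained fractions match the eigenvalue ratios
  expect_equal(fit$explained[1:4], ev$values[1:4] / total_var,
               tolerance = 1e-8)
  # reconstruction error from top-4 components = total - retained variance
  retained <- sum(ev$values[1:4])
  recon_err <- sum(ev$values[-(1:4)][ev$values[-(1:4)] > 0])
  expect_equal(total_var - retained, recon_err, tolerance = 1e-8)
})

test_that("variance_target picks the fewest sufficient components", {
  set.seed(8)
  frames <- lapply(1:12, function(i) matrix(runif(64, 0, 255), 8, 8))
  fit <- fit_frame_pca(frames,
                       keyframe_config(variance_target = 0.8, downsample = 8))
  m <- fit$n_used
  expect_gte(sum(fit$explained[1:m]), 0.8)
  if (m > 1) expect_lt(sum(fit$explained[1:(m - 1)]), 0.8)
})

test_that("keyframe selection returns one nearest-to-centroid frame per cluster", {
  # two point clouds far apart, k = 2: one keyframe per cloud, each the
  # exhaustively-verified nearest point to its cloud centroid
  set.seed(5)
  emb <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 50), 20, 2))
  ks <- select_keyframes(emb, keyframe_config(k = 2, seed = 1))
  expect_length(ks$indices, 2)
  expect_equal(length(unique(ks$cluster_assignments[ks$indices])), 2)
  for (i in ks$indices) {
    cl <- ks$cluster_assignments[i]
    members <- which(ks$cluster_assignments == cl)
    cen <- colMeans(emb[members, , drop = FALSE])
    d <- sqrt(colSums((t(emb[members, , drop = FALSE]) - cen)^2))
    expect_equal(sqrt(sum((emb[i, ] - cen)^2)), min(d))
  }
})

test_that("selection handles degenerate sizes and is deterministic", {
  set.seed(2)
  emb <- matrix(rnorm(10), 5, 2)
  ks <- select_keyframes(emb, keyframe_config(k = 10))
  expect_equal(ks$indices, 1:5)  # fewer frames than clusters: all returned
  expect_error(keyframe_config(k = 0), "k must be")

  emb2 <- matrix(rnorm(120), 60, 2)
  a <- select_keyframes(emb2, keyframe_config(k = 8, seed = 7))
  b <- select_keyframes(emb2, keyframe_config(k = 8, seed = 7))
  expect_identical(a$indices, b$indices)
  expect_true(all(diff(a$indices) > 0))
})

test_that("a long video is summarized into exactly k default keyframes", {
  v <- fx_long_video()
  probe <- filter_domain(v, domain_filter_config(Inf))
  dcal <- calibrate_threshold(attr(probe, "scores"), v$flags$is_in_domain,
                              "keep_below")
  kept <- filter_domain(v, domain_filter_config(dcal$threshold))
  pb <- filter_blur(v, kept, blur_config(0))
  bcal <- calibrate_threshold(attr(pb, "scores"),
                              !v$flags$is_blurred[kept], "keep_above")
  kept <- filter_blur(v, kept, blur_config(bcal$threshold))
  expect_gt(length(kept), 100)
  frames <- lapply(kept, function(i) video_frame(v, i))
  fit <- fit_frame_pca(frames, keyframe_config())
  ks <- select_keyframes(fit$embeddings, keyframe_config(),
                         frame_indices = as.integer(kept))
  expect_length(ks$indices, 100)
  expect_equal(anyDuplicated(ks$indices), 0)
  expect_true(all(ks$indices %in% kept))
})
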
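test_that("histograms are normalized and match a direct counting oracle", {
  # constant image: all mass in bin 1
  h <- compute_histogram(array(0, c(8, 8, 3)), bins = 8)
  expect_equal(colSums(h$p), rep(1, 3), tolerance = 1e-9)
  expect_true(all(h$p[1, ] > 0.999))
  expect_true(all(h$p[-1, ] < 1e-6))

  # half 0 / half 255 with 2 bins: (0.5, 0.5) per channel
  img <- array(rep(c(0, 255), each = 32), c(8, 8, 3))
  h2 <- compute_histogram(img, bins = 2)
  expect_equal(as.numeric(h2$p), rep(0.5, 6), tolerance = 1e-6)

  # random image vs brute-force bin/count/normalize loop
  set.seed(42)
  img <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
  bins <- 16; eps <- 1e-8
  h3 <- compute_histogram(img, bins = bins, epsilon = eps)
  for (ch in 1:3) {
    counts <- rep(eps, bins)
    for (v in as.numeric(img[, , ch])) {
      b <- min(floor(v / 256 * bins) + 1, bins)
      counts[b] <- counts[b] + 1
    }
    expect_equal(h3$p[, ch], counts / sum(counts), tolerance = 1e-12)
  }

  expect_error(compute_histogram(array(0, c(0, 0, 3))), "empty")
})

test_that("KL divergence matches hand evaluation and Gibbs' inequality", {
  mk <- function(p) structure(list(p = matrix(p, ncol = 1),
                                   bins = length(p), channels = 1L),
                              class = "frame_histogram")
  p <- mk(c(0.5, 0.5)); q <- mk(c(0.9, 0.1))
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, q),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-12)
  expect_error(kl_divergence(p, mk(c(0.2, 0.3, 0.5))), "disagree")

  # nonnegative on 1,000 random histogram pairs; zero only when identical
  set.seed(7)
  for (i in 1:1000) {
    a <- runif(8) + 1e-8; a <- a / sum(a)
    b <- runif(8) + 1e-8; b <- b / sum(b)
    expect_gte(kl_divergence(mk(a), mk(b)), 0)
  }
})

test_that("Laplacian variance behaves as a sharpness score", {
  expect_equal(laplacian_variance(matrix(57, 20, 20)), 0)
  expect_equal(laplacian_variance(array(100, c(10, 10, 3))), 0)

  # sharp checkerboard strictly sharper than its Gaussian-blurred copy
  cb <- 255 * outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  blurred <- as.array(EBImage::gblur(cb, sigma = 2))
  expect_gt(laplacian_variance(cb), laplacian_variance(blurred))

  # arbitrary 5x5 integer image vs hand-rolled convolve-then-variance loop
  set.seed(1)
  img <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  refl <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  lap <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    lap[i, j] <- img[refl(i - 1, 5), j] + img[refl(i + 1, 5), j] +
      img[i, refl(j - 1, 5)] + img[i, refl(j + 1, 5)] - 4 * img[i, j]
  expect_equal(laplacian_variance(img), var(as.numeric(lap)))
})

test_that("domain filter keeps in-domain frames and honors the central-frame rule", {
  # identical frames: all scores 0, all kept
  frames <- array(rep(as.integer(round(runif(96 * 64 * 3) * 255)), 5),
                  c(96, 64, 3, 5))
  kept <- filter_domain(frames, domain_filter_config(kl_threshold = 1e-6))
  expect_equal(as.integer(kept), 1:5)
  expect_equal(max(attr(kept, "scores")), 0)

  # single-frame video: kept
  one <- frames[, , , 1, drop = FALSE]
  expect_equal(as.integer(filter_domain(one, domain_filter_config(0))), 1L)

  # synthetic video with known flags: calibrated threshold recovers them
  v <- fx_video()
  probe <- filter_domain(v, domain_filter_config(Inf))
  cal <- calibrate_threshold(attr(probe, "scores"), v$flags$is_in_domain,
                             "keep_below")
  expect_true(cal$separable)
  kept2 <- filter_domain(v, domain_filter_config(cal$threshold))
  expect_equal(as.integer(kept2), which(v$flags$is_in_domain))
})

test_that("blur filter recovers ground-truth sharpness flags", {
  v <- fx_video()
  idx <- which(v$flags$is_in_domain)
  probe <- filter_blur(v, idx, blur_config(0))
  cal <- calibrate_threshold(attr(probe, "scores"),
                             !v$flags$is_blurred[idx], "keep_above")
  expect_true(cal$separable)
  kept <- filter_blur(v, idx, blur_config(cal$threshold))
  expect_equal(as.integer(kept),
               which(v$flags$is_in_domain & !v$flags$is_blurred))

  # threshold 0 keeps everything
  expect_equal(as.integer(filter_blur(v, idx, blur_config(0))), idx)

  # all-constant frames with positive threshold: empty result
  const <- array(80L, c(16, 16, 3, 4))
  expect_length(filter_blur(const, cfg = blur_config(1)), 0)
})

test_that("both filters return strictly increasing subsets of their input", {
  v <- fx_video()
  dcfg <- domain_filter_config(2)
  kd <- filter_domain(v, dcfg)
  expect_true(all(diff(kd) > 0))
  expect_true(all(kd %in% seq_len(nrow(v$flags))))
  kb <- filter_blur(v, kd, blur_config(30))
  expect_true(all(diff(kb) > 0))
  expect_true(all(kb %in% kd))
})
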
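# Closed-form parameter-count oracle: (3*3*c_in + 1)*c_out per conv layer,
# (n_in + 1)*n_out per dense layer, independent of the package's layer walk.
oracle_param_count <- function(input_shape, blocks, fc_sizes, n_classes) {
  h <- input_shape[1]; w <- input_shape[2]; c_in <- input_shape[3]
  total <- 0
  for (b in blocks) {
    for (i in seq_len(b[1])) {
      total <- total + (3 * 3 * c_in + 1) * b[2]
      c_in <- b[2]
    }
    h <- h / 2; w <- w / 2
  }
  n_in <- h * w * c_in
  for (s in c(fc_sizes, n_classes)) {
    total <- total + (n_in + 1) * s
    n_in <- s
  }
  total
}
vgg_blocks <- list(c(2, 64), c(2, 128), c(3, 256), c(3, 512), c(3, 512))

test_that("VGG-16 factory reproduces the canonical parameter count", {
  m <- build_vgg16(c(224, 224, 3), n_classes = 1000)
  expect_equal(m$param_count,
               oracle_param_count(c(224, 224, 3), vgg_blocks,
                                  c(4096, 4096), 1000))
  expect_equal(m$param_count, 138357544)

  # 1- vs 3-channel input differ by exactly the first conv layer's extra taps
  m1 <- build_vgg16(c(224, 224, 1), n_classes = 1000)
  expect_equal(m$param_count - m1$param_count, 2 * 3 * 3 * 64)

  # oracle also holds for arbitrary architectures, e.g. the tiny default
  t0 <- build_tiny()
  expect_equal(t0$param_count,
               oracle_param_count(c(32, 32, 1),
                                  list(c(1, 8), c(1, 16), c(1, 32)), 64, 4))
  expect_lt(t0$param_count, 1e6)
})

test_that("spatial dimensions halve per pool down to 7x7x512", {
  shp <- layer_shapes(build_vgg16(c(224, 224, 3), n_classes = 1000))
  pools <- shp$out_shape[shp$type == "pool"]
  expect_equal(pools, c("112x112x64", "56x56x128", "28x28x256",
                        "14x14x512", "7x7x512"))
  expect_equal(shp$out_shape[shp$type == "flatten"], "25088")
  expect_error(architecture_spec(c(100, 100, 3), vgg_blocks, 10, 4),
               "divisible")
  expect_error(architecture_spec(c(224, 224, 2), vgg_blocks, 10, 4),
               "channels")
})

test_that("softmax outputs are valid probability rows", {
  m <- init_weights(build_tiny(), seed = 4)
  set.seed(4)
  imgs <- lapply(1:5, function(i) matrix(runif(32 * 32, 0, 255), 32, 32))
  P <- predict_proba(m, c(imgs, imgs[1]))
  expect_equal(dim(P), c(6, 4))
  expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-6)
  expect_true(all(P > 0 & P < 1))
  # duplicated image gives an identical row
  expect_equal(P[6, ], P[1, ], ignore_attr = TRUE)
})

test_that("a tiny model overfits a small separable image set", {
  d <- fx_images()
  ds <- batch_spectral(d$images, d$labels, "gray_g")
  cfg <- train_config(learning_rate = 1e-3, batch_size = 16, epochs = 30,
                      augment = FALSE, n_trials = 1, seed = 3)
  m <- suppressWarnings(train(build_tiny(), ds$images, ds$labels, cfg,
                              mode = "gray_g"))
  expect_gt(tail(m$history$train_acc, 1), 0.9)
})

test_that("training is deterministic and respects channel contracts", {
  d <- fx_images()
  sub <- unlist(lapply(unique(d$labels),
                       function(cl) which(d$labels == cl)[1:10]))
  ds <- batch_spectral(d$images[sub], d$labels[sub], "gray_g")
  cfg <- train_config(learning_rate = 1e-3, batch_size = 8, epochs = 2,
                      n_trials = 1, seed = 12)
  m1 <- suppressWarnings(train(build_tiny(), ds$images, ds$labels, cfg))
  m2 <- suppressWarnings(train(build_tiny(), ds$images, ds$labels, cfg))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)

  # epochs = 0: initialized model, empty history
  m0 <- train(build_tiny(), ds$images, ds$labels,
              train_config(epochs = 0, n_trials = 1, seed = 1))
  expect_equal(nrow(m0$history), 0)
  expect_false(is.null(m0$weights))

  # 3-channel mode into a 1-channel architecture is an error naming both
  expect_error(train(build_tiny(), ds$images, ds$labels, cfg,
                     mode = "masked_g"), "channel")
  ds3 <- batch_spectral(d$images[sub], d$labels[sub], "masked_g")
  expect_error(suppressWarnings(train(build_tiny(), ds3$images, ds3$labels,
                                      cfg)), "expects 1")
})
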
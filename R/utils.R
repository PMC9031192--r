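#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp kmeans rnorm runif var sd aggregate
#' @importFrom utils head write.csv read.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All seeded package functions route through this
# so that no function disturbs global reproducibility.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic integer mix used to derive per-video / per-trial seeds from a
# master seed. Keeps every derived seed in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  for (p in parts) h <- (h * 48271 + (p %% m) + 11) %% m
  as.integer(h + 1)
}

# Clip numeric array/vector into [lo, hi].
clip <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Bilinear resize of a 2-D or 3-D image array
#'
#' Thin wrapper around [EBImage::resize()] keeping the height x width (x
#' channels) array convention used throughout the package.
#'
#' @param img numeric array, `H x W` or `H x W x C`.
#' @param h,w target height and width in pixels.
#' @return array of dimension `h x w (x C)`.
#' @export
resize_image <- function(img, h, w) {
  out <- EBImage::resize(img, w = h, h = w)  # EBImage's first dim is our rows
  as.array(out)
}

# Convert H x W x 3 uint8-range array to weighted-luminance grayscale (H x W).
luminance <- function(frame) {
  0.2989 * frame[, , 1] + 0.5870 * frame[, , 2] + 0.1140 * frame[, , 3]
}
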
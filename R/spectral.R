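#' The seven spectral channel modes
#'
#' Input renderings used for the color-dependence study. `gray_weighted` is
#' the weighted luminance combination
#' `g = 0.2989 R + 0.5870 G + 0.1140 B`; `gray_r` / `gray_g` / `gray_b`
#' extract one channel as a single-plane image; `masked_r` / `masked_g` /
#' `masked_b` keep three channels but zero the other two, so the network sees
#' a 3-channel tensor carrying information in only one channel. The nominal
#' wavelength bands are red 618-780 nm, green 497-570 nm, blue 427-476 nm
#' (documentation metadata only; no spectral physics is computed).
#'
#' @return character vector of the seven mode names.
#' @export
channel_modes <- function() {
  c("gray_weighted", "gray_r", "gray_g", "gray_b",
    "masked_r", "masked_g", "masked_b")
}

# channels the network input has under each mode
mode_channels <- function(mode) {
  if (startsWith(mode, "gray")) 1L else 3L
}

wavelength_bands <- function() {
  data.frame(channel = c("R", "G", "B"),
             nm_low = c(618, 497, 427), nm_high = c(780, 570, 476))
}

LUMA_WEIGHTS <- c(R = 0.2989, G = 0.5870, B = 0.1140)

#' Render an RGB frame in one spectral channel mode
#'
#' Output pixels are kept in floating point on the input's 0-255 scale; no
#' rounding or quantization is applied (scaling to `[0, 1]` happens at network
#' input).
#'
#' @param frame numeric `H x W x 3` array.
#' @param mode one of [channel_modes()].
#' @return object of class `"spectral_image"`: list with `pixels` (`H x W`
#'   matrix for gray modes, `H x W x 3` array for masked modes), `mode`, and
#'   `bands` (wavelength metadata).
#' @export
to_spectral <- function(frame, mode) {
  mode <- match.arg(mode, channel_modes())
  if (length(dim(frame)) != 3 || dim(frame)[3] != 3)
    stopf("to_spectral() needs an H x W x 3 frame; got dimensions [%s]",
          paste(dim(frame), collapse = ", "))
  px <- switch(mode,
    gray_weighted = luminance(frame),
    gray_r = frame[, , 1],
    gray_g = frame[, , 2],
    gray_b = frame[, , 3],
    masked_r = { f <- frame; f[, , 2:3] <- 0; f },
    masked_g = { f <- frame; f[, , c(1, 3)] <- 0; f },
    masked_b = { f <- frame; f[, , 1:2] <- 0; f })
  structure(list(pixels = px, mode = mode, bands = wavelength_bands()),
            class = "spectral_image")
}

#' Convert a labeled image set to one spectral mode
#'
#' @param images list of `H x W x 3` arrays.
#' @param labels class label per image.
#' @param mode one of [channel_modes()].
#' @return list with `images` (list of pixel arrays), `labels` (unchanged) and
#'   `mode`.
#' @export
batch_spectral <- function(images, labels, mode) {
  if (length(images) == 0) stopf("empty dataset")
  stopifnot(length(images) == length(labels))
  list(images = lapply(images, function(f) to_spectral(f, mode)$pixels),
       labels = labels, mode = mode)
}
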
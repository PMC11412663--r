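# Signal preprocessing before segmentation and measurement. The fixed stage
# order is: rolling-ball background subtraction, then CLAHE local contrast
# enhancement, then (segmentation channel only) the DoG filter.

#' Rolling-ball parameters
#'
#' @param radius_px ball radius in pixels (positive). The default of 50 px
#'   is the common particle-analysis default; the value is deliberately
#'   exposed because the appropriate radius depends on object size (it must
#'   exceed the radius of the largest foreground object).
#' @return object of class `rolling_ball_params`.
#' @export
rolling_ball_params <- function(radius_px = 50) {
  if (!is.numeric(radius_px) || length(radius_px) != 1 || !is.finite(radius_px) ||
      radius_px <= 0)
    stop("rolling-ball radius must be a positive number")
  structure(list(radius_px = radius_px), class = "rolling_ball_params")
}

#' CLAHE parameters
#'
#' Defaults match the workflow's published settings: 30-pixel blocks, 256
#' histogram bins, maximum slope 3, fast (block-interpolated) variant.
#'
#' @param block_size_px side of the square histogram blocks, in pixels.
#' @param histogram_bins number of histogram bins.
#' @param max_slope clip limit expressed as the maximum slope of the
#'   cumulative mapping; the per-bin clip is
#'   `max_slope * block_px / histogram_bins`.
#' @return object of class `clahe_params`.
#' @export
clahe_params <- function(block_size_px = 30, histogram_bins = 256,
                         max_slope = 3.0) {
  if (block_size_px < 2) stop("CLAHE block size must be >= 2")
  if (histogram_bins < 2) stop("CLAHE needs at least 2 histogram bins")
  if (max_slope <= 0) stop("CLAHE max slope must be positive")
  structure(list(block_size_px = as.integer(block_size_px),
                 histogram_bins = as.integer(histogram_bins),
                 max_slope = max_slope),
            class = "clahe_params")
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image by a
#' ball-shaped (spherical-cap) structuring element of the given radius and
#' subtracts it, clipping at 0. Flat offsets are pure background
#' (`rolling_ball_subtract(x + c) == rolling_ball_subtract(x)`), so uneven
#' illumination slower than the ball curvature is removed.
#'
#' @param channel 2D numeric matrix.
#' @param params a [rolling_ball_params()].
#' @return matrix of the same size, values >= 0; integral inputs give
#'   integral outputs.
#' @export
rolling_ball_subtract <- function(channel, params = rolling_ball_params()) {
  if (!inherits(params, "rolling_ball_params")) params <- rolling_ball_params(params)
  if (!is.matrix(channel) || length(channel) == 0)
    stop("`channel` must be a non-empty matrix")
  storage.mode(channel) <- "double"
  bg <- cpp_grey_open_ball(channel, params$radius_px)
  out <- pmax(channel - bg, 0)
  if (all(channel == round(channel))) out <- round(out)
  out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Per-block histograms (`histogram_bins` bins over the dtype range) are
#' clipped at `max_slope * block_px / bins` with the clipped mass
#' redistributed uniformly; the cumulative mappings are applied with
#' bilinear interpolation between block centers (the "fast" variant).
#' Edge blocks come from a mirrored image so every block is full-size.
#'
#' @param channel 2D numeric matrix.
#' @param params a [clahe_params()].
#' @param value_range length-2 numeric giving the histogram/output range.
#'   When `NULL` the occupied data range is used, so the histogram bins
#'   resolve the values actually present (16-bit microscopy data rarely
#'   fills its dtype range); the output always stays within the input
#'   dtype range because `range(data)` is a subset of it.
#' @return matrix of the same size; output values stay within `value_range`.
#' @export
clahe <- function(channel, params = clahe_params(), value_range = NULL) {
  stopifnot(inherits(params, "clahe_params"))
  if (!is.matrix(channel) || length(channel) == 0)
    stop("`channel` must be a non-empty matrix")
  storage.mode(channel) <- "double"
  block <- params$block_size_px
  if (block > min(dim(channel))) {
    block <- min(dim(channel))
    warning("CLAHE block larger than image; shrunk to ", block, " px")
  }
  if (is.null(value_range)) value_range <- default_value_range(channel)
  cpp_clahe(channel, block, params$histogram_bins, params$max_slope,
            value_range[1], value_range[2])
}

default_value_range <- function(channel) range(channel)

#' Preprocess one channel (background subtraction, then CLAHE)
#'
#' @param channel 2D numeric matrix.
#' @param rb a [rolling_ball_params()], or `NULL` to skip subtraction.
#' @param cl a [clahe_params()], or `NULL` to skip CLAHE (the published
#'   ablation switch).
#' @param value_range forwarded to [clahe()].
#' @return processed matrix.
#' @export
preprocess_channel <- function(channel, rb = rolling_ball_params(),
                               cl = clahe_params(), value_range = NULL) {
  out <- channel
  if (!is.null(rb)) out <- rolling_ball_subtract(out, rb)
  if (!is.null(cl)) out <- clahe(out, cl, value_range = value_range)
  out
}

#' Preprocess every channel of a stack
#'
#' All channels go through the same background subtraction and CLAHE steps
#' (not only the segmentation channel), so measured intensities refer to the
#' processed signal.
#'
#' @param stack an [image_stack()].
#' @inheritParams preprocess_channel
#' @return an [image_stack()] with processed channels.
#' @export
preprocess_stack <- function(stack, rb = rolling_ball_params(),
                             cl = clahe_params()) {
  stopifnot(inherits(stack, "image_stack"))
  channels <- lapply(stack$channels, preprocess_channel, rb = rb, cl = cl)
  image_stack(channels, channel_names = stack$channel_names,
              pixel_size_um = stack$pixel_size_um,
              bit_depth = stack$bit_depth)
}
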
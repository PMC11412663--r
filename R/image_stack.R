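#' Multi-channel image stack
#'
#' Container for a named multi-channel 2D intensity image. Channels are
#' numeric matrices indexed `[row, col]` (row = y downward, col = x
#' rightward, top-left origin). All channels must share dimensions; channel
#' names are unique and index-aligned.
#'
#' @param channels list of 2D numeric matrices, all the same size, values >= 0.
#' @param channel_names character vector of unique non-empty names, one per
#'   channel. Defaults to `"ch1".."chN"`.
#' @param pixel_size_um microns per pixel (positive). Defaults to 1 so that
#'   areas stay in pixel units (and `IntDen == RawIntDen`).
#' @param bit_depth `"8"`, `"16"` or `"float"`. Inferred from the data when
#'   `NULL`: integral values within \[0, 255\] give `"8"`, within
#'   \[0, 65535\] give `"16"`, anything else `"float"`.
#' @return an object of class `image_stack` with fields `channels`
#'   (named list), `channel_names`, `pixel_size_um`, `bit_depth`.
#' @export
image_stack <- function(channels, channel_names = NULL, pixel_size_um = 1.0,
                        bit_depth = NULL) {
  if (!is.list(channels) || length(channels) == 0)
    stop("`channels` must be a non-empty list of matrices")
  channels <- lapply(channels, function(m) {
    if (!is.matrix(m)) stop("each channel must be a 2D matrix")
    storage.mode(m) <- "double"
    m
  })
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channel arrays must share identical dimensions")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(channels))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != length(channels))
    stop("`channel_names` must have one name per channel")
  if (anyDuplicated(channel_names) || any(!nzchar(channel_names)))
    stop("channel names must be unique and non-empty")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive number")
  if (min(vapply(channels, min, numeric(1))) < 0)
    stop("pixel values must be >= 0")
  if (is.null(bit_depth)) bit_depth <- infer_bit_depth(channels)
  bit_depth <- match.arg(as.character(bit_depth), c("8", "16", "float"))
  names(channels) <- channel_names
  structure(
    list(channels = channels, channel_names = channel_names,
         pixel_size_um = pixel_size_um, bit_depth = bit_depth),
    class = "image_stack")
}

infer_bit_depth <- function(channels) {
  mx <- max(vapply(channels, max, numeric(1)), 0)
  integral <- all(vapply(channels, function(m) all(m == round(m)), logical(1)))
  if (!integral) return("float")
  if (mx <= 255) "8" else if (mx <= 65535) "16" else "float"
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d channel(s), %d x %d px, %s-bit, %.4g um/px\n",
              length(x$channels), d[1], d[2], x$bit_depth, x$pixel_size_um))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' Extract one channel as a matrix
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @return numeric matrix.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel) && !channel %in% stack$channel_names)
    stop(sprintf("channel '%s' not in stack (have: %s)", channel,
                 paste(stack$channel_names, collapse = ", ")))
  stack$channels[[channel]]
}

dtype_max <- function(bit_depth) {
  switch(bit_depth, "8" = 255, "16" = 65535, "float" = Inf)
}
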
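#' Read a multi-channel image stack from TIFF file(s)
#'
#' Accepts either several single-/multi-page TIFF files (channels in file
#' order, pages flattened per file) or one multi-page TIFF (page order
#' defines channel order). All pages must share dimensions and bit depth.
#'
#' @param paths character vector of TIFF paths.
#' @param channel_names optional character vector naming the channels; must
#'   match the channel count. When absent, names stored in the files'
#'   ImageDescription are used if unique, otherwise `"ch1".."chN"`.
#' @param pixel_size_um optional microns per pixel; overrides any value
#'   recorded in the file metadata. Defaults to 1 when absent everywhere.
#' @return an [image_stack()].
#' @export
read_stack <- function(paths, channel_names = NULL, pixel_size_um = NULL) {
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("file does not exist: ", paste(missing_files, collapse = ", "))
  channels <- list()
  descs <- character(0)
  src <- character(0)
  fmt <- character(0)
  meta_ps <- NULL
  for (p in paths) {
    pages <- read_tiff(p)
    for (pg in pages) {
      channels[[length(channels) + 1]] <- pg$image
      descs <- c(descs, pg$description)
      src <- c(src, p)
      fmt <- c(fmt, if (pg$sample_format == 3L) "float" else as.character(pg$bits))
    }
  }
  d0 <- dim(channels[[1]])
  for (i in seq_along(channels)) {
    di <- dim(channels[[i]])
    if (!identical(di, d0))
      stop(sprintf("dimension mismatch: '%s' is %dx%d, expected %dx%d",
                   src[i], di[1], di[2], d0[1], d0[2]))
  }
  if (length(unique(fmt)) > 1)
    stop("mixed TIFF bit depths across channels: ",
         paste(unique(fmt), collapse = ", "))
  # parse channel name / pixel size lines recorded by write_stack
  parsed <- parse_descriptions(descs)
  if (!is.null(parsed$pixel_size_um)) meta_ps <- parsed$pixel_size_um
  if (is.null(channel_names)) {
    nm <- parsed$names
    if (!anyNA(nm) && !anyDuplicated(nm) && all(nzchar(nm)))
      channel_names <- nm
  } else if (length(channel_names) != length(channels)) {
    stop(sprintf("%d channel names given for %d channels",
                 length(channel_names), length(channels)))
  }
  ps <- if (!is.null(pixel_size_um)) pixel_size_um
        else if (!is.null(meta_ps)) meta_ps else 1.0
  image_stack(channels, channel_names = channel_names, pixel_size_um = ps,
              bit_depth = fmt[1])
}

parse_descriptions <- function(descs) {
  nm <- rep(NA_character_, length(descs))
  ps <- NULL
  for (i in seq_along(descs)) {
    if (is.na(descs[i]) || !nzchar(descs[i])) next
    lines <- strsplit(descs[i], "\n", fixed = TRUE)[[1]]
    nm[i] <- lines[1]
    psl <- grep("^pixel_size_um=", lines, value = TRUE)
    if (length(psl)) ps <- as.numeric(sub("^pixel_size_um=", "", psl[1]))
  }
  list(names = nm, pixel_size_um = ps)
}

#' Write an image stack to TIFF
#'
#' Writes either one multi-page TIFF (channel names stored in each page's
#' ImageDescription) or one file per channel, suffixed by channel name.
#' Round-trips pixel values exactly for integer data; float data within
#' exact float32 representation.
#'
#' @param stack an [image_stack()].
#' @param path output path (for `as_single_stack = FALSE` the channel name
#'   is inserted before the extension).
#' @param as_single_stack write one multi-page file (default) or one file
#'   per channel.
#' @param compression `"none"` or `"LZW"`.
#' @return character vector of written paths, invisibly.
#' @export
write_stack <- function(stack, path, as_single_stack = TRUE,
                        compression = c("none", "LZW")) {
  compression <- match.arg(compression)
  stopifnot(inherits(stack, "image_stack"))
  descs <- paste0(stack$channel_names, "\npixel_size_um=",
                  format(stack$pixel_size_um, digits = 15))
  if (as_single_stack) {
    write_tiff(stack$channels, path, compression = compression,
               bit_depth = stack$bit_depth, descriptions = descs)
    return(invisible(path))
  }
  base <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  safe <- gsub("[^A-Za-z0-9_.-]", "_", stack$channel_names)
  paths <- paste0(base, "_", safe, ".tif")
  for (i in seq_along(paths))
    write_tiff(stack$channels[[i]], paths[i], compression = compression,
               bit_depth = stack$bit_depth, descriptions = descs[i])
  invisible(paths)
}
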
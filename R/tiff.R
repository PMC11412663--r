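# Minimal grayscale TIFF codec (baseline + LZW, single- and multi-page).
# No TIFF-capable R package exists in the target runtime, so the subset of
# the format this package needs is implemented here: little-endian writing;
# reading of either byte order; 8/16-bit unsigned and 32-bit float samples;
# strip layout; Compression 1 (none) and 5 (LZW, with horizontal-predictor
# support on read). Interoperability is exercised in the test suite against
# an independent reference implementation.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL

u16le <- function(x) {
  x <- as.integer(round(x))
  x[x > 32767L] <- x[x > 32767L] - 65536L
  writeBin(x, raw(), size = 2, endian = "little")
}

u32le <- function(x) {
  x <- as.numeric(x)
  ifelse_big <- x > 2147483647
  if (any(ifelse_big)) x[ifelse_big] <- x[ifelse_big] - 4294967296
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

encode_pixels <- function(m, bits) {
  v <- t(m)  # TIFF scanlines are row-major
  if (bits == 8L) {
    as.raw(as.integer(round(v)))
  } else if (bits == 16L) {
    u16le(as.vector(v))
  } else {
    writeBin(as.numeric(v), raw(), size = 4, endian = "little")
  }
}

tiff_bits <- function(bit_depth) {
  switch(bit_depth, "8" = 8L, "16" = 16L, "float" = 32L,
         stop("unsupported bit depth: ", bit_depth))
}

#' Write grayscale TIFF pages
#'
#' Low-level writer used by [write_stack()]. Writes one single- or
#' multi-page little-endian grayscale TIFF.
#'
#' @param images a matrix or list of matrices (pages), identical sizes.
#' @param path output file path.
#' @param compression `"none"` or `"LZW"`.
#' @param bit_depth `"8"`, `"16"` or `"float"`; inferred when `NULL`.
#' @param descriptions optional character vector, one ImageDescription per
#'   page (used to carry channel names and pixel size).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(images, path, compression = c("none", "LZW"),
                       bit_depth = NULL, descriptions = NULL) {
  compression <- match.arg(compression)
  if (is.matrix(images)) images <- list(images)
  if (is.null(bit_depth)) bit_depth <- infer_bit_depth(images)
  bits <- tiff_bits(bit_depth)
  comp_code <- if (compression == "LZW") 5L else 1L
  n_pages <- length(images)
  if (!is.null(descriptions) && length(descriptions) != n_pages)
    stop("`descriptions` must have one entry per page")

  pages <- vector("list", n_pages)
  for (i in seq_len(n_pages)) {
    m <- images[[i]]
    raw_px <- encode_pixels(m, bits)
    if (comp_code == 5L) raw_px <- cpp_lzw_encode(raw_px)
    if (length(raw_px) %% 2 == 1) raw_px <- c(raw_px, as.raw(0))  # word-align
    desc <- if (is.null(descriptions)) "" else descriptions[i]
    desc_raw <- c(charToRaw(enc2utf8(desc)), as.raw(0))
    # keep the value out-of-line (readers treat counts <= 4 as inline)
    if (length(desc_raw) < 6) desc_raw <- c(desc_raw, raw(6 - length(desc_raw)))
    if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
    pages[[i]] <- list(h = nrow(m), w = ncol(m), px = raw_px, desc = desc_raw,
                       nbytes = length(raw_px))
  }

  n_entries <- 11L
  ifd_size <- 2L + 12L * n_entries + 4L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(c(charToRaw("II"), u16le(42L), u32le(8L)), con)
  pos <- 8
  for (i in seq_len(n_pages)) {
    p <- pages[[i]]
    desc_off <- pos + ifd_size
    strip_off <- desc_off + length(p$desc)
    next_ifd <- if (i < n_pages) strip_off + p$nbytes else 0
    entry <- function(tag, type, count, value_raw) {
      stopifnot(length(value_raw) <= 4)
      c(u16le(tag), u16le(type), u32le(count),
        value_raw, raw(4 - length(value_raw)))
    }
    ifd <- c(
      u16le(n_entries),
      entry(256L, 4L, 1L, u32le(p$w)),                        # ImageWidth
      entry(257L, 4L, 1L, u32le(p$h)),                        # ImageLength
      entry(258L, 3L, 1L, u16le(bits)),                       # BitsPerSample
      entry(259L, 3L, 1L, u16le(comp_code)),                  # Compression
      entry(262L, 3L, 1L, u16le(1L)),                         # BlackIsZero
      entry(270L, 2L, length(p$desc), u32le(desc_off)),       # Description
      entry(273L, 4L, 1L, u32le(strip_off)),                  # StripOffsets
      entry(277L, 3L, 1L, u16le(1L)),                         # SamplesPerPixel
      entry(278L, 4L, 1L, u32le(p$h)),                        # RowsPerStrip
      entry(279L, 4L, 1L, u32le(p$nbytes)),                   # StripByteCounts
      entry(339L, 3L, 1L, u16le(if (bits == 32L) 3L else 1L)),# SampleFormat
      u32le(next_ifd))
    writeBin(c(ifd, p$desc, p$px), con)
    pos <- strip_off + p$nbytes
  }
  invisible(path)
}

#' Read a grayscale TIFF file
#'
#' Low-level reader used by [read_stack()]. Handles single- and multi-page
#' grayscale TIFFs (both byte orders), 8/16-bit unsigned or 32-bit float
#' samples, strip layout, no compression or LZW (with optional horizontal
#' predictor).
#'
#' @param path file path.
#' @return list with one element per page, each a list of `image`
#'   (numeric matrix), `bits`, `sample_format` and `description`
#'   (`NA` when absent).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 8) stop("not a TIFF file (too short): ", path)
  order_tag <- rawToChar(bytes[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  rd_int <- function(off, size, n = 1L, signed = FALSE) {
    readBin(bytes[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = if (size == 4L) TRUE else signed, endian = endian)
  }
  if (rd_int(2, 2) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- rd_int(4, 4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- rd_int(ifd_off, 2)
    tags <- list()
    for (k in seq_len(n_entries)) {
      eo <- ifd_off + 2 + 12 * (k - 1)
      tag <- rd_int(eo, 2)
      type <- rd_int(eo + 2, 2)
      count <- rd_int(eo + 4, 4)
      tags[[as.character(tag)]] <- list(type = type, count = count, off = eo + 8)
    }
    getv <- function(tag, default = NULL) {
      e <- tags[[as.character(tag)]]
      if (is.null(e)) return(default)
      if (e$type < 1 || e$type > 5) return(default)
      size <- TIFF_TYPE_SIZES[e$type]
      total <- size * e$count
      voff <- if (total <= 4) e$off else rd_int(e$off, 4)
      if (e$type == 2L) {  # ASCII
        s <- bytes[(voff + 1):(voff + e$count)]
        nul <- which(s == 0)
        len <- if (length(nul)) nul[1] - 1L else length(s)
        return(rawToChar(s[seq_len(len)]))
      }
      if (e$type == 5L) {  # RATIONAL
        num <- rd_int(voff, 4, e$count * 2)
        return(num[seq(1, by = 2, length.out = e$count)] /
               num[seq(2, by = 2, length.out = e$count)])
      }
      rd_int(voff, size, e$count, signed = FALSE)
    }
    w <- getv(256); h <- getv(257)
    if (is.null(w) || is.null(h)) stop("invalid TIFF: missing dimensions in ", path)
    bits <- getv(258, 1L)[1]
    comp <- getv(259, 1L)
    spp <- getv(277, 1L)
    if (spp != 1L) stop("only single-sample grayscale TIFF supported: ", path)
    if (!is.null(tags[["322"]])) stop("tiled TIFF not supported: ", path)
    if (!comp %in% c(1L, 5L))
      stop("unsupported TIFF compression code ", comp, " in ", path)
    fmt <- getv(339, 1L)
    predictor <- getv(317, 1L)
    strip_off <- getv(273); strip_cnt <- getv(279)
    rps <- getv(278, h)
    if (is.null(strip_off) || is.null(strip_cnt))
      stop("invalid TIFF: missing strip layout in ", path)
    bytespp <- bits %/% 8L
    vals <- numeric(0)
    rows_done <- 0L
    for (s in seq_along(strip_off)) {
      nrows <- min(rps, h - rows_done)
      raw_s <- bytes[(strip_off[s] + 1):(strip_off[s] + strip_cnt[s])]
      if (comp == 5L) raw_s <- cpp_lzw_decode(raw_s, nrows * w * bytespp)
      raw_s <- raw_s[seq_len(nrows * w * bytespp)]
      if (bits == 32L && fmt == 3L) {
        v <- readBin(raw_s, "numeric", n = nrows * w, size = 4, endian = endian)
      } else if (bits %in% c(8L, 16L) && fmt == 1L) {
        v <- readBin(raw_s, "integer", n = nrows * w, size = bytespp,
                     signed = FALSE, endian = endian)
      } else {
        stop("unsupported TIFF sample layout (bits=", bits, ", format=", fmt,
             ") in ", path)
      }
      if (predictor == 2L) {  # undo horizontal differencing, row by row
        v <- as.vector(apply(matrix(v, nrow = nrows, byrow = TRUE), 1, cumsum))
        if (bits == 8L) v <- v %% 256 else if (bits == 16L) v <- v %% 65536
      }
      vals <- c(vals, v)
      rows_done <- rows_done + nrows
    }
    img <- t(matrix(vals, nrow = w, ncol = h))
    pages[[length(pages) + 1]] <-
      list(image = img, bits = bits, sample_format = fmt,
           description = getv(270, NA_character_))
    ifd_off <- rd_int(ifd_off + 2 + 12 * n_entries, 4)
  }
  pages
}
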
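# Tile-grid handling: whole-slide scanners export a batch of per-field TIFF
# tiles whose grid position is encoded in the filename (Vectra writes a
# bracketed "[x,y]" token). Positions are parsed, missing grid cells are
# filled with black (all-zero) tiles and the grid is stitched by abutting
# placement into one mosaic per channel.

#' Default tile filename pattern
#'
#' Captures the bracketed `[x,y]` token used by Vectra-exported tiles, e.g.
#' `sample_[3,7].tif`. The two integer capture groups are (column, row).
#' @export
DEFAULT_TILE_PATTERN <- "\\[(\\d+),(\\d+)\\]"

#' Parse tile grid positions from filenames
#'
#' Extracts (column, row) coordinates from each filename using a regular
#' expression with two integer capture groups (column first). Coordinates
#' are shifted so the minima are 0; gaps in the numbering are preserved
#' (they become black-tile columns/rows after [fill_missing_tiles()]).
#'
#' @param filenames character vector.
#' @param pattern regular expression with two integer capture groups.
#' @return data.frame with columns `filename`, `col`, `row` (0-based).
#' @export
parse_tile_positions <- function(filenames, pattern = DEFAULT_TILE_PATTERN) {
  m <- regmatches(filenames, regexec(pattern, filenames))
  bad <- vapply(m, function(g) length(g) < 3, logical(1))
  if (any(bad))
    stop("no coordinates found in filename(s): ",
         paste(filenames[bad], collapse = ", "))
  col <- vapply(m, function(g) as.integer(g[2]), integer(1))
  row <- vapply(m, function(g) as.integer(g[3]), integer(1))
  key <- paste(col, row, sep = ",")
  if (anyDuplicated(key)) {
    clash <- key[duplicated(key)][1]
    stop("duplicate tile coordinates (", clash, "): ",
         paste(filenames[key == clash], collapse = ", "))
  }
  data.frame(filename = filenames, col = col - min(col), row = row - min(row),
             stringsAsFactors = FALSE)
}

#' Tile grid
#'
#' @param tiles named list of tiles; each tile is a matrix or a list of
#'   per-channel matrices. Names are `"row,col"` 0-based strings as
#'   produced by [tile_key()].
#' @param n_rows,n_cols grid extent; defaults to max index + 1.
#' @return object of class `tile_grid`.
#' @export
tile_grid <- function(tiles, n_rows = NULL, n_cols = NULL) {
  if (length(tiles) == 0) stop("grid must contain at least one tile")
  rc <- do.call(rbind, lapply(strsplit(names(tiles), ",", fixed = TRUE),
                              as.integer))
  tiles <- lapply(tiles, function(t) if (is.matrix(t)) list(t) else t)
  shp <- lapply(tiles, function(t) dim(t[[1]]))
  h <- shp[[1]][1]; w <- shp[[1]][2]
  nch <- length(tiles[[1]])
  for (i in seq_along(tiles)) {
    if (!identical(shp[[i]], c(h, w)) || length(tiles[[i]]) != nch)
      stop("non-uniform tile shapes: tile ", names(tiles)[i])
  }
  structure(list(
    tiles = tiles,
    tile_height = h, tile_width = w, n_channels = nch,
    n_rows = if (is.null(n_rows)) max(rc[, 1]) + 1L else as.integer(n_rows),
    n_cols = if (is.null(n_cols)) max(rc[, 2]) + 1L else as.integer(n_cols)),
    class = "tile_grid")
}

#' @rdname tile_grid
#' @param row,col 0-based grid indices.
#' @export
tile_key <- function(row, col) paste(row, col, sep = ",")

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d grid, %d/%d tiles present, tiles %d x %d x %dch\n",
              x$n_rows, x$n_cols, length(x$tiles), x$n_rows * x$n_cols,
              x$tile_height, x$tile_width, x$n_channels))
  invisible(x)
}

#' Load a tile grid from a directory of TIFF tiles
#'
#' @param dir directory containing tile TIFFs.
#' @param pattern filename pattern, see [parse_tile_positions()].
#' @return a `tile_grid`.
#' @export
read_tile_grid <- function(dir, pattern = DEFAULT_TILE_PATTERN) {
  files <- list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE)
  if (!length(files)) stop("no TIFF tiles found in ", dir)
  pos <- parse_tile_positions(files, pattern)
  tiles <- list()
  for (i in seq_len(nrow(pos))) {
    pages <- read_tiff(file.path(dir, pos$filename[i]))
    tiles[[tile_key(pos$row[i], pos$col[i])]] <- lapply(pages, `[[`, "image")
  }
  tile_grid(tiles)
}

#' Fill missing grid positions with black tiles
#'
#' Inserts all-zero ("black", devoid of any fluorescence signal) tiles at
#' every absent (row, col) position so the grid becomes rectangular.
#'
#' @param grid a [tile_grid()].
#' @return a complete `tile_grid`.
#' @export
fill_missing_tiles <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  black <- replicate(grid$n_channels,
                     matrix(0, grid$tile_height, grid$tile_width),
                     simplify = FALSE)
  for (r in seq_len(grid$n_rows) - 1L)
    for (cc in seq_len(grid$n_cols) - 1L) {
      k <- tile_key(r, cc)
      if (is.null(grid$tiles[[k]])) grid$tiles[[k]] <- black
    }
  grid
}

#' Stitch a complete tile grid into a mosaic
#'
#' Tiles are placed by abutment (no overlap, no blending): tile (r, c)
#' occupies rows `[r*H, (r+1)*H)` and columns `[c*W, (c+1)*W)` of the
#' mosaic. Pixel values are copied unchanged, so the mosaic conserves the
#' pixel sum of the provided tiles.
#'
#' @param grid a rectangular [tile_grid()] (run [fill_missing_tiles()] first
#'   if positions are missing).
#' @param channel_names,pixel_size_um passed to [image_stack()].
#' @return an [image_stack()] of size `(n_rows*H) x (n_cols*W)`.
#' @export
stitch_tiles <- function(grid, channel_names = NULL, pixel_size_um = 1.0) {
  stopifnot(inherits(grid, "tile_grid"))
  missing_keys <- setdiff(
    as.vector(outer(seq_len(grid$n_rows) - 1L, seq_len(grid$n_cols) - 1L,
                    tile_key)),
    names(grid$tiles))
  if (length(missing_keys))
    stop("grid is not rectangular; missing tiles at: ",
         paste(missing_keys, collapse = " "),
         " (run fill_missing_tiles() first)")
  H <- grid$tile_height; W <- grid$tile_width
  channels <- replicate(grid$n_channels,
                        matrix(0, grid$n_rows * H, grid$n_cols * W),
                        simplify = FALSE)
  for (r in seq_len(grid$n_rows) - 1L)
    for (cc in seq_len(grid$n_cols) - 1L) {
      t <- grid$tiles[[tile_key(r, cc)]]
      for (ch in seq_len(grid$n_channels))
        channels[[ch]][r * H + seq_len(H), cc * W + seq_len(W)] <- t[[ch]]
    }
  image_stack(channels, channel_names = channel_names,
              pixel_size_um = pixel_size_um)
}
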
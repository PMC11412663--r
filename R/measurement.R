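# Per-cell measurement. Conventions (fixed so downstream scatter plots are
# reproducible): pixel coordinates are 0-based pixel centers, x = column
# (rightward), y = row (downward), origin top-left; centroids are reported
# in pixels; areas/perimeters/axes are calibrated by pixel size. The
# perimeter is the 8-connected outline chain length (straight steps 1,
# diagonal steps sqrt(2)); the convex area is the area of the convex hull
# of the object pixels' corner points (so solidity never exceeds 1).

# clockwise Moore neighborhood starting west: W NW N NE E SE S SW
MOORE <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                ncol = 2, byrow = TRUE)

# outline chain length of a single connected object given its pixel
# coordinates (1-based rows/cols); Moore boundary tracing with state-repeat
# termination
chain_perimeter <- function(rows, cols) {
  n <- length(rows)
  if (n == 1) return(4)  # unit pixel square outline
  r0 <- min(rows) - 2L; c0 <- min(cols) - 2L
  H <- max(rows) - min(rows) + 5L; W <- max(cols) - min(cols) + 5L
  sub <- matrix(FALSE, H, W)
  sub[cbind(rows - r0, cols - c0)] <- TRUE
  ord <- order(rows, cols)
  b <- c(rows[ord[1]] - r0, cols[ord[1]] - c0)
  cdir <- 1L  # backtrack points west (background by construction)
  total <- 0
  # the walk may take a few pre-cycle steps before settling on the closed
  # boundary cycle; the perimeter is the cycle length only, so remember the
  # accumulated length at each visited state and subtract on state repeat
  seen <- new.env(hash = TRUE, parent = emptyenv())
  repeat {
    key <- paste(b[1], b[2], cdir)
    if (!is.null(seen[[key]])) {
      total <- total - seen[[key]]
      break
    }
    seen[[key]] <- total
    found <- FALSE
    for (k in 1:7) {
      d <- ((cdir - 1L + k) %% 8L) + 1L
      nb <- b + MOORE[d, ]
      if (sub[nb[1], nb[2]]) {
        prev_d <- ((cdir - 1L + k - 1L) %% 8L) + 1L
        bt <- b + MOORE[prev_d, ]
        total <- total + sqrt(sum((nb - b)^2))
        delta <- bt - nb
        cdir <- which(MOORE[, 1] == delta[1] & MOORE[, 2] == delta[2])
        b <- nb
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (cannot happen for n > 1 connected)
  }
  total
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# lattice points inside a polygon (ray casting); the polygon is inflated by
# a hair around its centroid so points exactly on an edge count as inside
points_in_polygon <- function(px, py, vx, vy) {
  mx <- mean(vx); my <- mean(vy)
  s <- 1 + 1e-9
  vx <- mx + (vx - mx) * s; vy <- my + (vy - my) * s
  inside <- rep(FALSE, length(px))
  j <- length(vx)
  for (i in seq_along(vx)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

convex_area_px <- function(rows, cols) {
  # pixels whose centers fall within the convex hull of the object's pixel
  # centers: a pixel-count convex area, so solidity never exceeds 1
  if (length(rows) <= 2 ||
      all(rows == rows[1]) || all(cols == cols[1]) ||
      { dr <- rows - rows[1]; dc <- cols - cols[1]
        all(dr * dc[2] == dc * dr[2]) && (any(dr != 0) || any(dc != 0)) }) {
    return(length(rows))  # collinear set: hull is the pixel run itself
  }
  h <- grDevices::chull(cols, rows)
  grid <- expand.grid(r = min(rows):max(rows), c = min(cols):max(cols))
  sum(points_in_polygon(grid$c, grid$r, cols[h], rows[h]))
}

#' Measure per-object geometry
#'
#' Computes, for every labeled object: area (pixel count times pixel area),
#' centroid (mean of 0-based pixel-center coordinates, reported in pixels),
#' outline chain perimeter, moment-matched ellipse axes (same area and
#' second central moments as the pixel set) and convex area.
#'
#' @param mask a [label_mask()].
#' @param pixel_size_um microns per pixel; 1 keeps areas in px^2.
#' @return data.frame with columns `cell`, `area`, `x`, `y`, `perimeter`,
#'   `major_axis`, `minor_axis`, `convex_area` (empty for an empty mask).
#' @export
measure_geometry <- function(mask, pixel_size_um = 1.0) {
  n <- n_objects(mask)
  out <- data.frame(cell = integer(0), area = numeric(0), x = numeric(0),
                    y = numeric(0), perimeter = numeric(0),
                    major_axis = numeric(0), minor_axis = numeric(0),
                    convex_area = numeric(0))
  if (n == 0) return(out)
  idx <- which(mask > 0L)
  labs <- as.vector(mask[idx])
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  ps <- pixel_size_um
  res <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- labs == i
    r <- rows[sel]; cc <- cols[sel]
    npix <- length(r)
    x0 <- cc - 1; y0 <- r - 1                    # 0-based pixel centers
    cx <- mean(x0); cy <- mean(y0)
    if (npix > 1) {
      covm <- stats::cov(cbind(x0, y0)) * (npix - 1) / npix  # population moments
      ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
      ev[ev < 0] <- 0
      a0 <- 4 * sqrt(ev[1]); b0 <- 4 * sqrt(ev[2])
      if (a0 > 0 && b0 > 0) {
        s <- sqrt(npix / (pi * a0 * b0 / 4))     # rescale to match pixel area
        a0 <- a0 * s; b0 <- b0 * s
      }
    } else {
      a0 <- 0; b0 <- 0
    }
    res[[i]] <- c(i, npix * ps^2, cx, cy, chain_perimeter(r, cc) * ps,
                  a0 * ps, b0 * ps, convex_area_px(r, cc) * ps^2)
  }
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("cell", "area", "x", "y", "perimeter", "major_axis",
                  "minor_axis", "convex_area")
  out$cell <- as.integer(out$cell)
  out
}

#' Shape descriptors
#'
#' Circularity `4*pi*area/perimeter^2` (clamped at 1, a perfect circle),
#' aspect ratio `major/minor`, roundness `4*area/(pi*major^2)` and solidity
#' `area/convex_area`. Degenerate inputs (zero perimeter or minor axis)
#' yield `NA` for the affected metrics; the caller flags, not drops, such
#' records.
#'
#' @param area,perimeter,major_axis,minor_axis,convex_area numeric vectors
#'   (recycled to common length).
#' @return data.frame with columns `circ`, `ar`, `round`, `solidity` and a
#'   logical `flagged`.
#' @export
shape_descriptors <- function(area, perimeter, major_axis, minor_axis,
                              convex_area) {
  circ <- ifelse(perimeter > 0, pmin(1, 4 * pi * area / perimeter^2), NA_real_)
  ar <- ifelse(minor_axis > 0, major_axis / minor_axis, NA_real_)
  rnd <- ifelse(major_axis > 0, 4 * area / (pi * major_axis^2), NA_real_)
  sol <- ifelse(convex_area > 0, area / convex_area, NA_real_)
  data.frame(circ = circ, ar = ar, round = rnd, solidity = sol,
             flagged = is.na(circ) | is.na(ar) | is.na(rnd) | is.na(sol))
}

#' Measure per-object intensity on one channel
#'
#' @param mask a [label_mask()].
#' @param channel 2D numeric matrix, same shape as the mask.
#' @param channel_name label stored in the output.
#' @param pixel_size_um pixel size used for the calibrated `int_den`
#'   (`area * mean`); with 1 um/px, `int_den == raw_int_den`.
#' @return data.frame with columns `cell`, `label`, `mean`, `raw_int_den`,
#'   `int_den`.
#' @export
measure_intensity <- function(mask, channel, channel_name = "ch1",
                              pixel_size_um = 1.0) {
  if (!all(dim(mask) == dim(channel)))
    stop(sprintf("mask (%dx%d) and channel (%dx%d) shapes differ",
                 nrow(mask), ncol(mask), nrow(channel), ncol(channel)))
  n <- n_objects(mask)
  if (n == 0)
    return(data.frame(cell = integer(0), label = character(0),
                      mean = numeric(0), raw_int_den = numeric(0),
                      int_den = numeric(0)))
  idx <- which(mask > 0L)
  labs <- factor(as.vector(mask[idx]), levels = seq_len(n))
  sums <- as.vector(rowsum(as.numeric(channel[idx]), labs))
  counts <- as.vector(table(labs))
  means <- sums / counts
  data.frame(cell = seq_len(n), label = channel_name, mean = means,
             raw_int_den = sums,
             int_den = counts * pixel_size_um^2 * means,
             stringsAsFactors = FALSE)
}

#' Background reference AOI
#'
#' Selects the reference region used for CTCF: either a manual rectangle
#' from the configuration, or (for non-interactive runs) the darkest
#' `window_px` x `window_px` window summed across channels, which must be
#' label-free.
#'
#' @param stack an [image_stack()].
#' @param mask optional [label_mask()]; the region must not intersect any
#'   labeled object.
#' @param mode `"manual"` (default when `rect` is given) or `"auto"`.
#' @param rect manual rectangle `c(x0, y0, width, height)` in 0-based pixel
#'   coordinates.
#' @param window_px square window side for auto mode.
#' @return object of class `background_aoi`: list with `region` and
#'   `per_channel_mean` (named numeric).
#' @export
select_background_aoi <- function(stack, mask = NULL,
                                  mode = c("manual", "auto"),
                                  rect = NULL, window_px = 20L) {
  stopifnot(inherits(stack, "image_stack"))
  mode <- if (missing(mode) && !is.null(rect)) "manual" else match.arg(mode)
  d <- dim(stack)
  if (mode == "manual") {
    if (is.null(rect) || length(rect) != 4)
      stop("manual mode needs `rect = c(x0, y0, width, height)`")
    x0 <- rect[1]; y0 <- rect[2]; w <- rect[3]; h <- rect[4]
    if (w <= 0 || h <= 0 || x0 < 0 || y0 < 0 || x0 + w > d[2] || y0 + h > d[1])
      stop("background rectangle does not fit in the image")
    rsel <- (y0 + 1):(y0 + h); csel <- (x0 + 1):(x0 + w)
  } else {
    if (window_px > min(d)) stop("auto window larger than image")
    total <- Reduce(`+`, stack$channels)
    wsum <- window_sums(total, window_px)
    if (!is.null(mask)) {
      occupied <- window_sums(matrix(as.numeric(mask > 0), d[1], d[2]),
                              window_px)
      wsum[occupied > 0] <- Inf
      if (all(!is.finite(wsum)))
        stop("no label-free window of ", window_px,
             " px found; use manual mode")
    }
    best <- which(wsum == min(wsum), arr.ind = TRUE)[1, ]  # row-major min tie
    y0 <- unname(best[1]) - 1L; x0 <- unname(best[2]) - 1L
    rect <- c(x0, y0, window_px, window_px)
    rsel <- (y0 + 1):(y0 + window_px); csel <- (x0 + 1):(x0 + window_px)
  }
  if (!is.null(mask) && any(mask[rsel, csel] > 0))
    stop("background rectangle overlaps labeled objects; choose another area")
  means <- vapply(stack$channels, function(ch) mean(ch[rsel, csel]),
                  numeric(1))
  structure(list(region = c(x0 = rect[1], y0 = rect[2], width = rect[3],
                            height = rect[4]),
                 per_channel_mean = means),
            class = "background_aoi")
}

# sliding-window sums via summed-area table; result [i,j] = sum of the
# w x w window whose top-left pixel is (i, j)
window_sums <- function(m, w) {
  sat <- apply(apply(m, 2, cumsum), 1, cumsum)  # sat[j, i] after transpose
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  H <- nrow(m); W <- ncol(m)
  i <- seq_len(H - w + 1); j <- seq_len(W - w + 1)
  sat[i + w, j + w, drop = FALSE] - sat[i + w, j, drop = FALSE] -
    sat[i, j + w, drop = FALSE] + sat[i, j, drop = FALSE]
}

#' Fill CTCF into a measurement table
#'
#' `CTCF = IntDen - Area * mean background fluorescence` of the record's
#' channel.
#'
#' @param records long measurement table from [measure_cells()].
#' @param background a [select_background_aoi()] result (or a named numeric
#'   of per-channel background means).
#' @return `records` with the `CTCF` column filled.
#' @export
compute_ctcf <- function(records, background) {
  bg <- if (inherits(background, "background_aoi")) background$per_channel_mean
        else background
  missing_ch <- setdiff(unique(records$Label), names(bg))
  if (length(missing_ch))
    stop("no background mean for channel(s): ",
         paste(missing_ch, collapse = ", "))
  records$CTCF <- records$IntDen - records$Area * unname(bg[records$Label])
  records
}

#' Measure all cells on all channels
#'
#' Produces the long single-cell table (one row per cell x channel) with
#' the fixed column order `Cell, Label, Area, Mean, X, Y, Circ., IntDen,
#' RawIntDen, AR, Round, Solidity, CTCF`. Geometry columns repeat across
#' channels by construction. Records with degenerate shape metrics keep
#' `NA` there and are listed in the `flagged_cells` attribute.
#'
#' @param stack an [image_stack()] (normally the preprocessed stack; pass
#'   the raw stack to measure raw intensities instead).
#' @param mask a [label_mask()] from [segment_cells()].
#' @param background optional [select_background_aoi()] result; when `NULL`
#'   the `CTCF` column is `NA`.
#' @return data.frame in Table-1 column order.
#' @export
measure_cells <- function(stack, mask, background = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (!all(dim(mask) == dim(stack)))
    stop("mask and stack dimensions differ")
  ps <- stack$pixel_size_um
  geom <- measure_geometry(mask, pixel_size_um = ps)
  shp <- shape_descriptors(geom$area, geom$perimeter, geom$major_axis,
                           geom$minor_axis, geom$convex_area)
  per_channel <- lapply(stack$channel_names, function(nm) {
    intens <- measure_intensity(mask, stack$channels[[nm]], nm,
                                pixel_size_um = ps)
    data.frame(Cell = geom$cell, Label = nm, Area = geom$area,
               Mean = intens$mean, X = geom$x, Y = geom$y,
               `Circ.` = shp$circ, IntDen = intens$int_den,
               RawIntDen = intens$raw_int_den, AR = shp$ar,
               Round = shp$round, Solidity = shp$solidity,
               CTCF = NA_real_, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, per_channel)
  rownames(records) <- NULL
  if (!is.null(background)) records <- compute_ctcf(records, background)
  attr(records, "flagged_cells") <- geom$cell[shp$flagged]
  records
}
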
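# Seeded synthetic multi-channel nuclei images with ground-truth label
# masks and per-cell marker truth tables, emulating the high-density (HD) /
# low-density (LD) crop regime used when benchmarking nucleus segmentation.
# Nuclei are Gaussian-profile disks; the ground-truth footprint is where the
# profile exceeds 10% of its amplitude, so the profile standard deviation is
# radius / sqrt(2 ln 10) and the footprint radius equals the nominal radius.

#' Synthetic fixture specification
#'
#' Defaults describe a realistic LD benchmark crop: 100 nuclei of mean
#' radius 7.5 px on a 400 x 400 px field, nuclear amplitude 1000 over a
#' background of 100 with Gaussian noise sd 100 (amplitude SNR 10),
#' rendered as 16-bit counts.
#'
#' @param width,height image size in pixels.
#' @param n_cells number of nuclei.
#' @param mean_radius_px mean nucleus radius (default 7.5 px, the
#'   benchmark's estimated mean cell radius at 1 um/px).
#' @param radius_sd radius standard deviation in px.
#' @param density_mode `"LD"` (hard-core spacing >= 2.5 x mean radius
#'   between centers) or `"HD"` (clustered, overlaps allowed).
#' @param nuclear_amplitude peak intensity of a nucleus above background.
#' @param background_level constant background offset.
#' @param gradient_amplitude amplitude of a linear left-to-right flatfield
#'   defect added to every channel (0 disables).
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param n_channels total channels; channel 1 is nuclear ("DAPI"), the
#'   rest are markers.
#' @param marker_positive_prob per-marker probability that a cell is
#'   positive (length `n_channels - 1`, recycled).
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(width = 400L, height = 400L, n_cells = 100L,
                         mean_radius_px = 7.5, radius_sd = 0.75,
                         density_mode = c("LD", "HD"),
                         nuclear_amplitude = 1000, background_level = 100,
                         gradient_amplitude = 0, noise_sd = 100,
                         n_channels = 3L, marker_positive_prob = 0.4,
                         seed = 1L) {
  density_mode <- match.arg(density_mode)
  stopifnot(width > 0, height > 0, n_cells > 0, mean_radius_px > 0,
            radius_sd >= 0, nuclear_amplitude > 0, background_level >= 0,
            gradient_amplitude >= 0, noise_sd >= 0, n_channels >= 1)
  marker_positive_prob <- rep_len(marker_positive_prob, max(0L, n_channels - 1L))
  if (any(marker_positive_prob < 0 | marker_positive_prob > 1))
    stop("marker_positive_prob must be in [0, 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells),
                 mean_radius_px = mean_radius_px, radius_sd = radius_sd,
                 density_mode = density_mode,
                 nuclear_amplitude = nuclear_amplitude,
                 background_level = background_level,
                 gradient_amplitude = gradient_amplitude,
                 noise_sd = noise_sd, n_channels = as.integer(n_channels),
                 marker_positive_prob = marker_positive_prob,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# hard-core (minimum-distance) center sampling for LD; clustered parents +
# Gaussian offspring for HD
sample_centers <- function(spec) {
  w <- spec$width; h <- spec$height; n <- spec$n_cells
  margin <- spec$mean_radius_px + 1
  if (spec$density_mode == "LD") {
    min_d2 <- (2.5 * spec$mean_radius_px)^2
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0L
    while (length(xs) < n) {
      attempts <- attempts + 1L
      if (attempts > 400L * n)
        stop("could not place ", n, " cells with the LD hard-core ",
             "constraint; reduce n_cells or use density_mode = \"HD\"")
      x <- runif(1, margin, w - margin); y <- runif(1, margin, h - margin)
      if (length(xs) == 0 || min((xs - x)^2 + (ys - y)^2) >= min_d2) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
  } else {
    n_parents <- max(1L, ceiling(n / 5))
    px <- runif(n_parents, margin, w - margin)
    py <- runif(n_parents, margin, h - margin)
    pick <- sample.int(n_parents, n, replace = TRUE)
    xs <- pmin(pmax(px[pick] + rnorm(n, 0, 2 * spec$mean_radius_px), margin),
               w - margin)
    ys <- pmin(pmax(py[pick] + rnorm(n, 0, 2 * spec$mean_radius_px), margin),
               h - margin)
  }
  cbind(x = xs, y = ys)
}

# add a Gaussian-profile disk in place; returns the modified image
render_blob <- function(img, cx, cy, amplitude, profile_sd) {
  h <- nrow(img); w <- ncol(img)
  ext <- ceiling(3.5 * profile_sd)
  rs <- max(1, floor(cy + 1 - ext)):min(h, ceiling(cy + 1 + ext))
  cs <- max(1, floor(cx + 1 - ext)):min(w, ceiling(cx + 1 + ext))
  d2 <- outer((rs - 1 - cy)^2, (cs - 1 - cx)^2, "+")
  img[rs, cs] <- img[rs, cs] + amplitude * exp(-d2 / (2 * profile_sd^2))
  img
}

#' Generate a synthetic nuclei fixture
#'
#' Renders the stack described by a [fixture_spec()]: nuclei as
#' Gaussian-profile disks on a constant background plus optional linear
#' flatfield gradient and Gaussian noise, quantized to 16-bit counts.
#' Marker channels light up Bernoulli-positive cells with lognormal
#' amplitudes. The ground-truth mask labels each nucleus footprint (profile
#' above 10% of amplitude); where footprints overlap, pixels go to the
#' closest center in radius-scaled distance (labels stay distinct in the
#' truth table even when footprints merge visually).
#'
#' @param spec a [fixture_spec()].
#' @return list with `stack` ([image_stack()]), `mask` (ground-truth
#'   [label_mask()]), `truth` (per cell x channel data.frame: `cell`, `x`,
#'   `y`, `radius`, `channel`, `positive`, `amplitude`) and `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  w <- spec$width; h <- spec$height; n <- spec$n_cells
  centers <- sample_centers(spec)
  radii <- pmax(3, rnorm(n, spec$mean_radius_px, spec$radius_sd))
  profile_sd <- radii / sqrt(2 * log(10))  # footprint (10% amplitude) at r

  gradient <- matrix(rep(spec$gradient_amplitude *
                           (seq_len(w) - 1) / max(1, w - 1),
                         each = h), h, w)

  # nuclear channel
  nuc <- matrix(0, h, w)
  for (i in seq_len(n))
    nuc <- render_blob(nuc, centers[i, 1], centers[i, 2],
                       spec$nuclear_amplitude, profile_sd[i])

  # marker channels: Bernoulli positivity, lognormal amplitude
  n_markers <- spec$n_channels - 1L
  positive <- matrix(FALSE, n, max(n_markers, 0L))
  amps <- matrix(0, n, max(n_markers, 0L))
  channels <- vector("list", spec$n_channels)
  for (m in seq_len(n_markers)) {
    positive[, m] <- runif(n) < spec$marker_positive_prob[m]
    amps[positive[, m], m] <-
      rlnorm(sum(positive[, m]), log(spec$nuclear_amplitude), 0.3)
    mk <- matrix(0, h, w)
    for (i in which(positive[, m]))
      mk <- render_blob(mk, centers[i, 1], centers[i, 2], amps[i, m],
                        profile_sd[i])
    channels[[m + 1L]] <- mk
  }
  channels[[1L]] <- nuc

  finish <- function(ch) {
    ch <- ch + spec$background_level + gradient
    if (spec$noise_sd > 0) ch <- ch + rnorm(h * w, 0, spec$noise_sd)
    matrix(pmin(pmax(round(ch), 0), 65535), h, w)
  }
  channels <- lapply(channels, finish)

  # ground-truth mask: nearest covering center in radius-scaled distance
  lab <- matrix(0L, h, w)
  best <- matrix(Inf, h, w)
  for (i in seq_len(n)) {
    r <- radii[i]; cx <- centers[i, 1]; cy <- centers[i, 2]
    rs <- max(1, floor(cy + 1 - r)):min(h, ceiling(cy + 1 + r))
    cs <- max(1, floor(cx + 1 - r)):min(w, ceiling(cx + 1 + r))
    d2 <- outer((rs - 1 - cy)^2, (cs - 1 - cx)^2, "+")
    score <- d2 / r^2
    hit <- score <= 1 & score < best[rs, cs]
    blk <- lab[rs, cs]
    blk[hit] <- i
    lab[rs, cs] <- blk
    bb <- best[rs, cs]
    bb[hit] <- score[hit]
    best[rs, cs] <- bb
  }

  names <- c("DAPI", if (n_markers > 0) paste0("marker", seq_len(n_markers)))
  truth <- do.call(rbind, lapply(seq_len(spec$n_channels), function(ch) {
    data.frame(cell = seq_len(n), x = centers[, 1], y = centers[, 2],
               radius = radii, channel = names[ch],
               positive = if (ch == 1) TRUE else positive[, ch - 1L],
               amplitude = if (ch == 1) spec$nuclear_amplitude
                           else amps[, ch - 1L],
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  # cells fully occluded by overlapping neighbours (HD mode) drop out of the
  # rendered mask; relabel densely but remember which cell each label is
  present <- sort(unique(lab[lab > 0L]))
  mask <- label_mask(lab, relabel = TRUE)
  attr(mask, "source_cells") <- present
  list(stack = image_stack(channels, channel_names = names,
                           pixel_size_um = 1.0, bit_depth = "16"),
       mask = mask, truth = truth, spec = spec)
}
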
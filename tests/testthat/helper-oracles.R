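# Independent oracles used by the tests. These deliberately re-derive the
# quantities from first principles (brute force, closed form, enumeration)
# and share no code with the implementation paths they check.

# grayscale opening by a non-flat ball structuring element, brute force
oracle_grey_open_ball <- function(img, radius) {
  H <- nrow(img); W <- ncol(img)
  R <- floor(radius)
  offs <- expand.grid(dy = -R:R, dx = -R:R)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$dy^2 - offs$dx^2)
  ero <- matrix(NA_real_, H, W)
  for (y in 1:H) for (x in 1:W) {
    yy <- y + offs$dy; xx <- x + offs$dx
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    ero[y, x] <- min(img[cbind(yy[ok], xx[ok])] - offs$h[ok])
  }
  dil <- matrix(NA_real_, H, W)
  for (y in 1:H) for (x in 1:W) {
    yy <- y + offs$dy; xx <- x + offs$dx
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    dil[y, x] <- max(ero[cbind(yy[ok], xx[ok])] + offs$h[ok])
  }
  dil
}

# classical global histogram equalization with cdf-min anchoring over the
# data range, `bins` bins
oracle_hist_eq <- function(img, bins = 256) {
  vmin <- min(img); vmax <- max(img)
  b <- pmin(floor((img - vmin) / (vmax - vmin) * bins), bins - 1)
  counts <- tabulate(as.vector(b) + 1L, nbins = bins)
  cdf <- cumsum(counts)
  cdfmin <- cdf[which(counts > 0)[1]]
  f <- (cdf - cdfmin) / (length(img) - cdfmin)
  f[f < 0] <- 0
  matrix(vmin + f[b + 1] * (vmax - vmin), nrow(img), ncol(img))
}

# normalized sampled 2D Gaussian kernel truncated at 4 sigma
oracle_gauss_kernel2d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  outer(w1, w1)
}

# exhaustive maximum one-to-one TP count over all assignments (<= 6 a side)
oracle_optimal_tp <- function(adm) {
  nr <- nrow(adm); np <- ncol(adm)
  if (nr == 0 || np == 0) return(0L)
  best <- 0L
  recurse <- function(i, used, tp) {
    if (tp + (nr - i + 1) <= best) return()  # bound
    if (i > nr) { best <<- max(best, tp); return() }
    recurse(i + 1L, used, tp)                # leave ref i unmatched
    for (j in which(adm[i, ])) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, tp + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(np), 0L)
  best
}

# random pair of label masks with <= max_obj partially overlapping disks a
# side; labels painted sequentially (later disks overwrite) then densified
random_mask_pair <- function(seed, size = 48L, max_obj = 6L) {
  set.seed(seed)
  paint <- function(n) {
    m <- matrix(0L, size, size)
    for (i in seq_len(n)) {
      r <- runif(1, 3, 7)
      cx <- runif(1, r, size - r); cy <- runif(1, r, size - r)
      d2 <- outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+")
      m[d2 <= r^2] <- i
    }
    label_mask(m)
  }
  list(ref = paint(sample.int(max_obj, 1)), pred = paint(sample.int(max_obj, 1)))
}

# minimal independent FCS reader (header offsets -> TEXT keywords -> DATA),
# written from the FCS 3.1 byte layout; shares nothing with write_fcs()
oracle_read_fcs <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  hdr <- rawToChar(bytes[1:58])
  version <- substr(hdr, 1, 6)
  offs <- as.numeric(vapply(0:5, function(k)
    trimws(substr(hdr, 11 + 8 * k, 18 + 8 * k)), character(1)))
  text <- rawToChar(bytes[(offs[1] + 1):(offs[2] + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts) - 1, by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, toupper(keys))
  n <- as.integer(kw[["$TOT"]]); p <- as.integer(kw[["$PAR"]])
  stopifnot(kw[["$DATATYPE"]] == "F", kw[["$MODE"]] == "L")
  endian <- if (kw[["$BYTEORD"]] == "1,2,3,4") "little" else "big"
  dstart <- as.numeric(kw[["$BEGINDATA"]]); dend <- as.numeric(kw[["$ENDDATA"]])
  vals32 <- readBin(bytes[(dstart + 1):(dend + 1)], "numeric",
                    n = n * p, size = 4, endian = endian)
  mat <- matrix(vals32, nrow = n, ncol = p, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(p), function(j) kw[[sprintf("$P%dN", j)]],
                          character(1))
  list(version = version, keywords = kw, data = mat)
}

# python bridge used for cross-implementation TIFF checks
python_bin <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  py
}

# small deterministic test stack
make_test_stack <- function(h = 20, w = 25, k = 3, seed = 42, bit_depth = "16") {
  set.seed(seed)
  mx <- if (bit_depth == "8") 255 else 65535
  channels <- replicate(k, {
    m <- matrix(sample.int(mx + 1, h * w, replace = TRUE) - 1, h, w)
    if (bit_depth == "float") m <- m + 0.25 else m
  }, simplify = FALSE)
  image_stack(channels, channel_names = paste0("C", seq_len(k)),
              bit_depth = bit_depth)
}
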
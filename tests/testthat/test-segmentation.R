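test_that("sigma_from_radius implements the adopted radius relation", {
  expect_equal(sigma_from_radius(7.5), 7.5 / sqrt(2 * log(255) - 1))
  expect_equal(sigma_from_radius(7.5), 2.362, tolerance = 5e-4)
  expect_error(sigma_from_radius(0), "positive")
  expect_error(sigma_from_radius(-1), "positive")
  # linear in the radius; scales with pixel size; constant overridable
  expect_equal(sigma_from_radius(15), 2 * sigma_from_radius(7.5))
  expect_equal(sigma_from_radius(7.5, pixel_size_um = 0.5),
               2 * sigma_from_radius(7.5))
  expect_equal(sigma_from_radius(10, constant = 4), 2.5)
})

test_that("DoG of a constant is zero and of an impulse is the kernel difference", {
  expect_equal(dog_filter(matrix(5, 30, 30), 2, 3), matrix(0, 30, 30),
               tolerance = 1e-12)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  got <- dog_filter(imp, 1.5, 2.5)
  want <- matrix(0, 41, 41)
  add_kernel <- function(m, k, sign) {
    r <- (nrow(k) - 1) / 2
    m[21 + (-r:r), 21 + (-r:r)] <- m[21 + (-r:r), 21 + (-r:r)] + sign * k
    m
  }
  want <- add_kernel(want, oracle_gauss_kernel2d(1.5), 1)
  want <- add_kernel(want, oracle_gauss_kernel2d(2.5), -1)
  expect_equal(got, want, tolerance = 1e-12)
  # mass conservation for interior-supported images
  set.seed(20)
  img <- matrix(0, 60, 60)
  img[25:35, 25:35] <- runif(121, 0, 100)
  expect_lt(abs(sum(dog_filter(img, 2, 3))), 1e-8)
  expect_error(dog_filter(imp, 2, 2), "sigma_high > sigma_low")
})

test_that("ISODATA threshold matches the intermeans fixed point", {
  half <- matrix(rep(c(0, 255), each = 128), 16, 16)
  t <- isodata_threshold(half)
  expect_lt(abs(t - 127.5), 255 / 256)  # within one bin width
  # two well-separated clusters
  set.seed(21)
  v <- matrix(c(rnorm(5000, 10, 5), rnorm(5000, 200, 5)), 100, 100)
  t2 <- isodata_threshold(v)
  expect_gt(t2, 80); expect_lt(t2, 130)
  # exhaustive-iteration oracle on the same sampled histogram
  oracle_iter <- function(x, bins = 256) {
    lo <- min(x); hi <- max(x); bw <- (hi - lo) / bins
    t <- (lo + hi) / 2
    repeat {
      below <- x <= t
      tn <- (mean(x[below]) + mean(x[!below])) / 2
      if (abs(tn - t) < bw) return(tn)
      t <- tn
    }
  }
  expect_equal(t2, oracle_iter(as.vector(v)), tolerance = 2 * (max(v) - min(v)) / 256)
  expect_error(isodata_threshold(matrix(7, 5, 5)), "degenerate histogram")
})

test_that("segment_cells recovers well-separated disks with IoU >= 0.5", {
  # 5 high-SNR disks of radius 7
  set.seed(22)
  img <- matrix(rnorm(120 * 120, 50, 5), 120, 120)
  centers <- cbind(x = c(20, 60, 100, 35, 85), y = c(20, 30, 25, 85, 90))
  truth <- matrix(0L, 120, 120)
  for (i in 1:5) {
    d2 <- outer((1:120 - 1 - centers[i, "y"])^2,
                (1:120 - 1 - centers[i, "x"])^2, "+")
    img <- img + 400 * (d2 <= 49)
    truth[d2 <= 49] <- i
  }
  img <- pmax(round(img), 0)
  truth <- label_mask(truth)
  params <- segmentation_params(2.36, 1.4, min_area_px = 10)
  mask <- segment_cells(preprocess_channel(img, rolling_ball_params(15),
                                           clahe_params()), params)
  expect_equal(n_objects(mask), 5)
  iou <- iou_matrix(truth, mask)
  expect_true(all(apply(iou, 1, max) >= 0.5))
  # min_area above the disk area kills everything
  big <- segmentation_params(2.36, 1.4, min_area_px = 5000)
  expect_equal(n_objects(segment_cells(img, big)), 0)
})

test_that("blank input yields zero objects with a warning", {
  expect_warning(m <- segment_cells(matrix(0, 40, 40),
                                    segmentation_params(2, 1.4)),
                 "degenerate")
  expect_equal(n_objects(m), 0)
})

test_that("label masks are dense and object count is monotone in min_area", {
  set.seed(23)
  img <- matrix(rnorm(80 * 80, 100, 10), 80, 80)
  for (i in 1:8) {
    cx <- sample(10:70, 1); cy <- sample(10:70, 1)
    d2 <- outer((1:80 - cy)^2, (1:80 - cx)^2, "+")
    img <- img + 300 * exp(-d2 / 18)
  }
  prev <- Inf
  for (ma in c(0, 10, 30, 100, 1e4)) {
    m <- segment_cells(img, segmentation_params(2, 1.5, min_area_px = ma))
    expect_lte(n_objects(m), prev)
    prev <- n_objects(m)
    expect_equal(max(as.vector(m), 0), n_objects(m))  # dense labels
  }
})

test_that("label_mask validates and densifies", {
  m <- matrix(0L, 4, 4); m[1, 1] <- 3L; m[4, 4] <- 7L
  lm <- label_mask(m)           # auto-densify
  expect_equal(n_objects(lm), 2)
  expect_setequal(unique(as.vector(lm)), c(0L, 1L, 2L))
  expect_error(label_mask(m, relabel = FALSE), "consecutive")
  expect_error(label_mask(matrix(-1L, 2, 2)), ">= 0")
})

test_that("segmentation_params validates its domain", {
  expect_error(segmentation_params(0, 1.4), "positive")
  expect_error(segmentation_params(2, 1), "> 1")
  expect_error(segmentation_params(2, 1.4, connectivity = 6), "4 or 8")
  p <- segmentation_params(2, 1.4)
  expect_equal(p$sigma_high, 2.8)
})
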
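two_square_masks <- function() {
  ref <- matrix(0L, 12, 12); pred <- matrix(0L, 12, 12)
  ref[2:4, 2:4] <- 1L; pred[2:4, 3:5] <- 1L    # 3x3 offset by one column
  ref[8:10, 8:10] <- 2L; pred[8:10, 8:10] <- 2L  # identical
  list(ref = label_mask(ref), pred = label_mask(pred))
}

test_that("IoU matrix matches hand counts", {
  m <- two_square_masks()
  iou <- iou_matrix(m$ref, m$pred)
  expect_equal(dim(iou), c(2L, 2L))
  expect_equal(iou[1, 1], 6 / 12)  # intersection 6, union 12
  expect_equal(iou[2, 2], 1)
  expect_equal(iou[1, 2], 0); expect_equal(iou[2, 1], 0)
  # identical masks give the identity pattern
  ii <- iou_matrix(m$ref, m$ref)
  expect_equal(ii, diag(2))
  expect_error(iou_matrix(m$ref, label_mask(matrix(0L, 5, 5))), "shapes")
})

test_that("matching thresholds and counts behave as specified", {
  m <- two_square_masks()
  iou <- iou_matrix(m$ref, m$pred)
  perfect <- match_at_threshold(iou_matrix(m$ref, m$ref), 0.9)
  expect_equal(c(perfect$tp, perfect$fp, perfect$fn), c(2L, 0L, 0L))
  at4 <- match_at_threshold(iou, 0.4)
  expect_equal(c(at4$tp, at4$fp, at4$fn), c(2L, 0L, 0L))
  at55 <- match_at_threshold(iou, 0.55)  # the 0.5-IoU pair drops out
  expect_equal(c(at55$tp, at55$fp, at55$fn), c(1L, 1L, 1L))
  # mere coexistence (IoU 0) never matches, even at t = 0
  disj <- matrix(0, 1, 1)
  m0 <- match_at_threshold(disj, 0)
  expect_equal(m0$tp, 0L)
  # invariants: tp+fn = n_ref, tp+fp = n_pred at any threshold
  for (t in seq(0, 1, 0.25)) {
    r <- match_at_threshold(iou, t)
    expect_equal(r$tp + r$fn, 2L)
    expect_equal(r$tp + r$fp, 2L)
  }
})

test_that("the four metrics implement the printed formulas exactly", {
  m <- seg_metrics(list(tp = 8, fp = 2, fn = 0))
  expect_equal(unname(m), c(0.8, 1, 0.8, 16 / 18))
  z <- seg_metrics(list(tp = 0, fp = 0, fn = 5))
  expect_equal(unname(z), c(0, 0, 0, 0))
  # exhaustive grid: formulas + harmonic-mean identity when TP > 0
  for (tp in 0:4) for (fp in 0:4) for (fn in 0:4) {
    got <- seg_metrics(list(tp = tp, fp = fp, fn = fn))
    expect_equal(got[["precision"]], if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(got[["recall"]], if (tp + fn > 0) tp / (tp + fn) else 0)
    expect_equal(got[["jaccard"]], if (tp + fp + fn > 0) tp / (tp + fp + fn) else 0)
    expect_equal(got[["fmeasure"]],
                 if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
    if (tp > 0) {
      p <- got[["precision"]]; r <- got[["recall"]]
      expect_equal(got[["fmeasure"]], 2 * p * r / (p + r))
    }
  }
})

test_that("benchmark curves have 21 points and are non-increasing", {
  m <- two_square_masks()
  cv <- benchmark_curve(m$ref, m$ref)
  expect_equal(nrow(cv), 21)
  expect_true(all(cv$precision == 1))
  cv2 <- benchmark_curve(m$ref, m$pred)
  expect_equal(cv2$recall[cv2$threshold <= 0.5], rep(1, 11))
  expect_equal(cv2$recall[cv2$threshold > 0.5], rep(0.5, 10))
  for (col in c("precision", "recall", "jaccard", "fmeasure"))
    expect_true(all(diff(cv2[[col]]) <= 1e-12))
  # property: random mask pairs stay monotone
  for (seed in 1:20) {
    mp <- random_mask_pair(seed)
    cv3 <- benchmark_curve(mp$ref, mp$pred)
    for (col in c("precision", "recall", "jaccard", "fmeasure"))
      expect_true(all(diff(cv3[[col]]) <= 1e-12), info = paste("seed", seed))
  }
})

test_that("optimal matching equals the exhaustive brute force; greedy never exceeds it", {
  greedy_deficits <- 0L
  for (seed in 1:60) {
    mp <- random_mask_pair(seed)
    iou <- iou_matrix(mp$ref, mp$pred)
    for (t in seq(0, 1, by = 0.1)) {
      greedy <- match_at_threshold(iou, t, method = "greedy")$tp
      optimal <- match_at_threshold(iou, t, method = "optimal")$tp
      brute <- oracle_optimal_tp(iou >= t & iou > 0)
      expect_equal(optimal, brute, info = paste("seed", seed, "t", t))
      expect_lte(greedy, optimal)
      if (greedy < optimal) greedy_deficits <- greedy_deficits + 1L
    }
  }
  # greedy is demonstrably suboptimal when one prediction straddles two
  # references -- which is why "optimal" is the default method
  expect_gt(greedy_deficits, 0L)
})

test_that("percent detected uses the all-predictions definition", {
  set.seed(50)
  ref <- matrix(0L, 40, 40)
  for (i in 1:10) ref[4 * i - 3 + 0:1, 5:6] <- i
  ref <- label_mask(ref)
  pred <- label_mask({p <- matrix(0L, 40, 40); p[1:2, 5:6] <- 1L
                      p[5:6, 5:6] <- 2L; p})
  expect_equal(percent_detected(ref, pred), 20)
  expect_equal(percent_detected(ref, ref), 100)
  # 64 predicted / 100 reference = 64 even without overlap
  big_ref <- label_mask(matrix(rep(1:100, each = 4), 20, 20))
  big_pred <- label_mask(matrix(rep(c(1:64, rep(0, 36)), each = 4), 20, 20))
  expect_equal(percent_detected(big_ref, big_pred), 64)
  expect_error(percent_detected(label_mask(matrix(0L, 5, 5)), pred),
               "no objects")
  # matched-only mode counts TP instead
  expect_equal(percent_detected(ref, pred, mode = "matched",
                                iou_threshold = 0.5), 20)
})

test_that("efficacy aggregation averages five measures and reports evolution", {
  df <- data.frame(method = c("A", "B"), region = "HD",
                   detected_fraction = c(0.2, 0.4), precision = c(0.9, 0.8),
                   recall = c(0.3, 0.6), jaccard = c(0.25, 0.5),
                   fmeasure = c(0.4, 0.65))
  out <- efficacy_summary(df, baselines = "A")
  expect_equal(out$average_efficacy, rowMeans(df[, 3:7]))
  expect_equal(out$evolution_vs_A[2],
               round((out$average_efficacy[2] / out$average_efficacy[1] - 1) * 100, 2))
  expect_equal(evolution_pct(0.5, 0.5), 0)
  expect_warning(expect_true(is.na(evolution_pct(0, 0.5))), "zero")
  expect_error(efficacy_summary(df[, -3]), "missing column")
})
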
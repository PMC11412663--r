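# Instance-segmentation benchmark: a predicted label mask is compared to a
# reference mask by one-to-one IoU matching; TP/FP/FN counts give the four
# quality metrics (precision, recall, Jaccard, F-measure) on an IoU
# threshold grid, plus the percent of detected objects and a Table-2-style
# efficacy aggregation.

#' Pairwise IoU matrix between two label masks
#'
#' `IoU(i, j) = |ref_i intersect pred_j| / |ref_i union pred_j|`; zero for
#' disjoint objects.
#'
#' @param reference,predicted [label_mask()] objects (or integer matrices)
#'   of identical shape.
#' @return `n_ref x n_pred` numeric matrix.
#' @export
iou_matrix <- function(reference, predicted) {
  if (!all(dim(reference) == dim(predicted)))
    stop("reference and predicted masks have different shapes")
  nr <- n_objects(reference); np <- n_objects(predicted)
  iou <- matrix(0, nr, np)
  if (nr == 0 || np == 0) return(iou)
  a_ref <- tabulate(reference[reference > 0L], nbins = nr)
  a_pred <- tabulate(predicted[predicted > 0L], nbins = np)
  sel <- reference > 0L & predicted > 0L
  if (any(sel)) {
    pairs <- paste(reference[sel], predicted[sel])
    tab <- table(pairs)
    ij <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
    inter <- as.vector(tab)
    iou[cbind(i, j)] <- inter / (a_ref[i] + a_pred[j] - inter)
  }
  iou
}

# full greedy one-to-one matching by descending IoU over all overlapping
# pairs; ties broken by smaller reference label, then smaller predicted
# label. Thresholding afterwards is equivalent to running greedy on the
# admissible subset because decisions only depend on higher-IoU pairs.
greedy_matching <- function(iou) {
  cand <- which(iou > 0, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(ref = integer(0), pred = integer(0), iou = numeric(0)))
  v <- iou[cand]
  ord <- order(-v, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  v <- v[ord]
  ref_free <- rep(TRUE, nrow(iou)); pred_free <- rep(TRUE, ncol(iou))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (ref_free[i] && pred_free[j]) {
      keep[k] <- TRUE
      ref_free[i] <- FALSE; pred_free[j] <- FALSE
    }
  }
  data.frame(ref = cand[keep, 1], pred = cand[keep, 2], iou = v[keep])
}

# maximum-cardinality bipartite matching on admissible pairs (augmenting
# paths); deterministic because vertices are tried in label order
optimal_tp <- function(adj) {
  nr <- nrow(adj)
  if (nr == 0 || ncol(adj) == 0) return(0L)
  match_pred <- integer(ncol(adj))
  visited <- logical(ncol(adj))
  aug <- function(i) {
    for (j in which(adj[i, ])) {
      if (visited[j]) next
      visited[j] <<- TRUE
      if (match_pred[j] == 0L || aug(match_pred[j])) {
        match_pred[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  tp <- 0L
  for (i in seq_len(nr)) {
    visited <- logical(ncol(adj))
    if (aug(i)) tp <- tp + 1L
  }
  tp
}

#' Match reference and predicted objects at one IoU threshold
#'
#' One-to-one matching over pairs with `IoU >= t` and `IoU > 0` (mere
#' coexistence never matches, including at t = 0). The default `"optimal"`
#' method computes the maximum-cardinality one-to-one matching on the
#' admissible pairs (the convention of standard instance-segmentation
#' benchmarks); `"greedy"` matches by descending IoU with deterministic
#' tie-breaks (smaller reference label, then smaller predicted label) and
#' can under-count TP when one prediction overlaps several references.
#' Matched pairs are TP; unmatched predicted objects are FP; unmatched
#' reference objects are FN.
#'
#' @param iou IoU matrix from [iou_matrix()].
#' @param t threshold in \[0, 1\].
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return list of class `match_result`: `threshold`, `tp`, `fp`, `fn`.
#' @export
match_at_threshold <- function(iou, t, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (!is.numeric(t) || t < 0 || t > 1) stop("`t` must be in [0, 1]")
  tp <- if (method == "greedy") {
    m <- greedy_matching(iou)
    sum(m$iou >= t)
  } else {
    optimal_tp(iou >= t & iou > 0)
  }
  structure(list(threshold = t, tp = as.integer(tp),
                 fp = ncol(iou) - as.integer(tp),
                 fn = nrow(iou) - as.integer(tp)),
            class = "match_result")
}

#' Benchmark metrics from TP/FP/FN
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `jaccard = TP/(TP+FP+FN)`, `fmeasure = 2TP/(2TP+FP+FN)`; any 0/0 is 0 by
#' convention (no predictions give precision 0, no matched reference gives
#' recall 0).
#'
#' @param m a `match_result` from [match_at_threshold()] (or a list with
#'   `tp`, `fp`, `fn`).
#' @return named numeric: precision, recall, jaccard, fmeasure.
#' @export
seg_metrics <- function(m) {
  tp <- m$tp; fp <- m$fp; fn <- m$fn
  if (any(c(tp, fp, fn) < 0)) stop("tp/fp/fn must be >= 0")
  safe <- function(num, den) if (den > 0) num / den else 0
  c(precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn),
    jaccard = safe(tp, tp + fp + fn),
    fmeasure = safe(2 * tp, 2 * tp + fp + fn))
}

#' Benchmark curve over the IoU threshold grid
#'
#' Evaluates [match_at_threshold()] + [seg_metrics()] on thresholds 0 to 1
#' with the given step (0.05 gives the standard 21-point grid). Every
#' metric series is monotonically non-increasing in the threshold.
#'
#' @param reference,predicted label masks of identical shape.
#' @param step grid step (default 0.05).
#' @param method matching method, see [match_at_threshold()].
#' @return data.frame of class `benchmark_curve` with columns `threshold`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `jaccard`, `fmeasure`.
#' @export
benchmark_curve <- function(reference, predicted, step = 0.05,
                            method = c("optimal", "greedy")) {
  method <- match.arg(method)
  iou <- iou_matrix(reference, predicted)
  thresholds <- seq(0, 1, by = step)
  rows <- lapply(thresholds, function(t) {
    m <- match_at_threshold(iou, t, method = method)
    c(threshold = t, tp = m$tp, fp = m$fp, fn = m$fn, seg_metrics(m))
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("benchmark_curve", "data.frame")
  out
}

#' Percent of detected objects
#'
#' `100 * n_predicted / n_reference` (the reference, usually manual
#' segmentation, represents 100% of the cells). All predicted objects
#' count, matched or not; `mode = "matched"` counts only predictions
#' matched at `iou_threshold` instead.
#'
#' @param reference,predicted label masks.
#' @param mode `"all"` (default) or `"matched"`.
#' @param iou_threshold threshold for `mode = "matched"`.
#' @return percentage (0-100 scale, can exceed 100 for over-segmentation).
#' @export
percent_detected <- function(reference, predicted, mode = c("all", "matched"),
                             iou_threshold = 0) {
  mode <- match.arg(mode)
  nr <- n_objects(reference)
  if (nr == 0) stop("reference mask has no objects")
  np <- if (mode == "all") {
    n_objects(predicted)
  } else {
    match_at_threshold(iou_matrix(reference, predicted), iou_threshold)$tp
  }
  100 * np / nr
}

#' Percent evolution between two efficacies
#'
#' `(b / a - 1) * 100`, reported to 2 decimals; `NA` (with a warning) when
#' the starting efficacy is zero.
#'
#' @param a,b efficacies (0-1 scale).
#' @return percentage, rounded to 2 decimals.
#' @export
evolution_pct <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- round((b / a - 1) * 100, 2)
  out[a == 0] <- NA_real_
  if (anyNA(out)) warning("undefined evolution from zero efficacy")
  out
}

#' Efficacy summary table
#'
#' Aggregates, per method and region, the five benchmark measurements taken
#' at a fixed IoU threshold -- detected fraction, precision, recall,
#' Jaccard, F-measure (all on the 0-1 scale) -- into their arithmetic mean
#' (`average_efficacy`), optionally adding percent-evolution columns
#' against baseline methods.
#'
#' @param df data.frame with columns `method`, `region`,
#'   `detected_fraction`, `precision`, `recall`, `jaccard`, `fmeasure`.
#' @param baselines optional character vector of method names; for each, a
#'   column `evolution_vs_<baseline>` compares every other method to it
#'   within the same region.
#' @return `df` with `average_efficacy` (and evolution columns) appended.
#' @export
efficacy_summary <- function(df, baselines = NULL) {
  need <- c("method", "region", "detected_fraction", "precision", "recall",
            "jaccard", "fmeasure")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  vals <- df[c("detected_fraction", "precision", "recall", "jaccard",
               "fmeasure")]
  df$average_efficacy <- rowMeans(as.matrix(vals))
  for (b in baselines) {
    col <- paste0("evolution_vs_", b)
    df[[col]] <- NA_real_
    for (r in unique(df$region)) {
      base <- df$average_efficacy[df$method == b & df$region == r]
      if (length(base) != 1) next
      sel <- df$region == r & df$method != b
      df[[col]][sel] <- evolution_pct(base, df$average_efficacy[sel])
    }
  }
  df
}
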
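# Evaluation metrics: PCK for keypoint localization, confusion-matrix metrics
# for the closure plan, and MAE / quadratic weighted kappa for the ordinal
# occluder-size prediction.

#' Percentage of correct keypoints (PCK)
#'
#' A predicted keypoint counts as correct when its Euclidean pixel error is at
#' most `alpha` times the length of the image's measuring scale in pixels
#' (inclusive threshold). The scale-relative normalization makes the metric
#' comparable across acquisitions with different zoom.
#'
#' @param pred,gt Lists of `keypoint_set` aligned case-by-case (or single
#'   sets).
#' @param scales List of `scale_info` per case (or a single one).
#' @param alpha Fraction of the scale-bar length used as the correctness
#'   radius (default 0.1).
#' @return Fraction of keypoints within threshold, in `[0, 1]`.
#' @export
pck <- function(pred, gt, scales, alpha = 0.1) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (inherits(pred, "keypoint_set")) pred <- list(pred)
  if (inherits(gt, "keypoint_set")) gt <- list(gt)
  if (inherits(scales, "scale_info")) scales <- list(scales)
  if (length(pred) != length(gt) || length(pred) != length(scales))
    stop("pred, gt and scales must align case-by-case", call. = FALSE)
  n_ok <- 0L; n <- 0L
  for (i in seq_along(pred)) {
    p <- pred[[i]]$points; g <- gt[[i]]$points
    if (nrow(p) != nrow(g))
      stop("keypoint counts differ in case ", i, call. = FALSE)
    thr <- alpha * scales[[i]]$scale_bar_length_px
    err <- sqrt(rowSums((p - g)^2))
    n_ok <- n_ok + sum(err <= thr)
    n <- n + length(err)
  }
  n_ok / n
}

#' Binary classification metrics for the closure plan
#'
#' Transcatheter closure is the positive class. F1 is the harmonic mean of
#' precision and recall, `2 * precision * recall / (precision + recall)`.
#' Undefined ratios (zero denominators) are returned as `NaN` with a warning.
#'
#' @param pred_plans,true_plans Character vectors of
#'   `"transcatheter"` / `"surgical"`.
#' @return List with `acc`, `f1`, `sensitivity`, `specificity`, `precision`,
#'   `recall`, and the confusion counts.
#' @export
classification_metrics <- function(pred_plans, true_plans) {
  if (length(pred_plans) == 0L || length(pred_plans) != length(true_plans))
    stop("inputs must be non-empty and of equal length", call. = FALSE)
  pos <- "transcatheter"
  tp <- sum(pred_plans == pos & true_plans == pos)
  fp <- sum(pred_plans == pos & true_plans != pos)
  fn <- sum(pred_plans != pos & true_plans == pos)
  tn <- sum(pred_plans != pos & true_plans != pos)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      NaN
    } else num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall/sensitivity")
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) {
    warning("F1 undefined", call. = FALSE); NaN
  } else 2 * precision * recall / (precision + recall)
  list(acc = (tp + tn) / (tp + fp + fn + tn), f1 = f1,
       sensitivity = recall,
       specificity = ratio(tn, tn + fp, "specificity"),
       precision = precision, recall = recall,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Mean absolute error of occluder sizes
#'
#' @param pred_sizes,true_sizes Numeric vectors of sizes in mm.
#' @return Mean absolute difference in mm.
#' @export
mae <- function(pred_sizes, true_sizes) {
  if (length(pred_sizes) == 0L || length(pred_sizes) != length(true_sizes))
    stop("inputs must be non-empty and of equal length", call. = FALSE)
  mean(abs(pred_sizes - true_sizes))
}

#' Quadratic weighted kappa for ordinal occluder sizes
#'
#' Chance-corrected agreement for ordinal outcomes:
#' `1 - sum(w * O) / sum(w * E)` with weights
#' `w[i, j] = (i - j)^2 / (K - 1)^2`, `O` the observed confusion matrix over
#' the ordered size levels, and `E` the outer product of the marginals scaled
#' to the same total (the standard Cohen-kappa expectation). Predicting a
#' 16 mm case as 14 mm is therefore penalized less than predicting it as
#' 10 mm. A degenerate expectation (e.g. constant vectors) yields `NaN` with
#' a warning.
#'
#' @param pred_sizes,true_sizes Vectors of sizes, all members of `levels`.
#' @param levels Strictly increasing ordinal levels (default `8:32` mm).
#' @return Kappa in `(-Inf, 1]`.
#' @export
qwk <- function(pred_sizes, true_sizes, levels = 8:32) {
  if (length(pred_sizes) == 0L || length(pred_sizes) != length(true_sizes))
    stop("inputs must be non-empty and of equal length", call. = FALSE)
  if (is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing", call. = FALSE)
  pi_ <- match(pred_sizes, levels)
  ti <- match(true_sizes, levels)
  if (anyNA(pi_) || anyNA(ti))
    stop("all sizes must be members of levels", call. = FALSE)
  K <- length(levels)
  O <- matrix(0, K, K)
  for (i in seq_along(pi_)) O[ti[i], pi_[i]] <- O[ti[i], pi_[i]] + 1
  w <- (outer(seq_len(K), seq_len(K), "-"))^2 / (K - 1)^2
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  den <- sum(w * E)
  if (den == 0) {
    warning("QWK undefined: degenerate expected matrix", call. = FALSE)
    return(NaN)
  }
  1 - sum(w * O) / den
}

#' Repeat an evaluation over several seeds and report mean +/- sd
#'
#' Mirrors the five-replicate reporting protocol: the supplied function is run
#' once per seed and each returned metric is summarized as mean and standard
#' deviation.
#'
#' @param fun Function taking a single integer seed and returning a named
#'   numeric vector (or list) of metrics.
#' @param seeds Integer vector of seeds (default `1:5`).
#' @return Data frame with columns `metric`, `mean`, `sd`, `n`.
#' @export
evaluate_replicates <- function(fun, seeds = 1:5) {
  runs <- lapply(seeds, function(s) unlist(fun(s)))
  mat <- do.call(rbind, runs)
  data.frame(metric = colnames(mat),
             mean = apply(mat, 2, mean),
             sd = apply(mat, 2, stats::sd),
             n = length(seeds), row.names = NULL)
}
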
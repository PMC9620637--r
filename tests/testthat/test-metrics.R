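test_that("PCK counts disparities against the scale-relative radius", {
  sc <- scale_info(mm_per_pixel = 0.2) # 50 px scale bar, radius 5 px
  gt <- keypoint_set("PSSAX", matrix(c(10, 20, 30, 10, 10, 10), 3, 2))
  expect_equal(pck(gt, gt, sc), 1.0)
  # one point exactly at the threshold counts as correct (inclusive)
  pred <- gt
  pred$points[1, ] <- pred$points[1, ] + c(3, 4) # error exactly 5 px
  expect_equal(pck(pred, gt, sc), 1.0)
  pred$points[1, ] <- gt$points[1, ] + c(3, 4.0001)
  expect_equal(pck(pred, gt, sc), 2 / 3)
  # 11 points across views, 2 beyond threshold -> 9/11
  gt_all <- list(gt,
                 keypoint_set("SXLAX", matrix(1:8 * 3, 4, 2)),
                 keypoint_set("A4C", matrix(1:8 * 2, 4, 2)))
  pred_all <- gt_all
  pred_all[[2]]$points[1, ] <- pred_all[[2]]$points[1, ] + 20
  pred_all[[3]]$points[4, ] <- pred_all[[3]]$points[4, ] + 20
  expect_equal(pck(pred_all, gt_all, list(sc, sc, sc)), 9 / 11)
})

test_that("PCK is monotone non-decreasing in alpha", {
  set.seed(41)
  sc <- scale_info(mm_per_pixel = 0.25)
  gt <- lapply(1:5, function(i)
    keypoint_set("A4C", matrix(runif(8, 5, 55), 4, 2)))
  pred <- lapply(gt, function(k)
    keypoint_set("A4C", k$points + matrix(rnorm(8, sd = 3), 4, 2)))
  scales <- rep(list(sc), 5)
  alphas <- seq(0.02, 0.5, by = 0.02)
  vals <- vapply(alphas, function(a) pck(pred, gt, scales, alpha = a),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("classification metrics match hand counts and the F1 formula", {
  # TP=3, FP=1, FN=1, TN=5
  truth <- c(rep("transcatheter", 4), rep("surgical", 6))
  pred <- c("transcatheter", "transcatheter", "transcatheter", "surgical",
            "transcatheter", rep("surgical", 5))
  m <- classification_metrics(pred, truth)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 2 * 0.75 * 0.75 / (0.75 + 0.75))
  expect_equal(m$acc, 0.8)
  expect_equal(m$specificity, 5 / 6)
  perfect <- classification_metrics(truth, truth)
  expect_equal(unlist(perfect[c("acc", "f1", "sensitivity",
                                "specificity")]),
               c(acc = 1, f1 = 1, sensitivity = 1, specificity = 1))
})

test_that("classification metrics agree with exhaustive single-case counts", {
  lv <- c("transcatheter", "surgical")
  for (p in lv) for (t in lv) {
    suppressWarnings(m <- classification_metrics(p, t))
    expect_equal(m$tp, as.integer(p == "transcatheter" &&
                                  t == "transcatheter"))
    expect_equal(m$fp, as.integer(p == "transcatheter" && t == "surgical"))
    expect_equal(m$fn, as.integer(p == "surgical" && t == "transcatheter"))
    expect_equal(m$tn, as.integer(p == "surgical" && t == "surgical"))
    expect_equal(m$acc, as.numeric(p == t))
  }
  # swapping the positive-class convention swaps sensitivity/specificity
  truth <- c(rep("transcatheter", 4), rep("surgical", 6))
  pred <- c(rep("transcatheter", 3), rep("surgical", 7))
  m1 <- classification_metrics(pred, truth)
  flip <- function(x) ifelse(x == "transcatheter", "surgical",
                             "transcatheter")
  m2 <- classification_metrics(flip(pred), flip(truth))
  expect_equal(m1$sensitivity, m2$specificity)
  expect_equal(m1$specificity, m2$sensitivity)
})

test_that("MAE is the mean absolute size difference", {
  expect_equal(mae(c(14, 16), c(14, 16)), 0)
  expect_equal(mae(16, 14), 2)
  expect_equal(mae(c(16, 10), c(14, 14)), 3)
  expect_error(mae(numeric(0), numeric(0)), "non-empty")
})

test_that("QWK matches an independent brute-force implementation", {
  qwk_oracle <- function(pred, true, levels) {
    K <- length(levels)
    n <- length(pred)
    num <- 0; den <- 0
    for (i in seq_len(K)) {
      for (j in seq_len(K)) {
        w <- (i - j)^2 / (K - 1)^2
        o <- sum(true == levels[i] & pred == levels[j])
        e <- sum(true == levels[i]) * sum(pred == levels[j]) / n
        num <- num + w * o
        den <- den + w * e
      }
    }
    1 - num / den
  }
  set.seed(71)
  levels <- 8:32
  for (rep in 1:100) {
    true <- sample(levels, 50, replace = TRUE)
    pred <- sample(levels, 50, replace = TRUE)
    expect_equal(qwk(pred, true, levels), qwk_oracle(pred, true, levels),
                 tolerance = 1e-12)
  }
})

test_that("QWK rewards perfection and penalizes by ordinal distance", {
  true <- c(8, 10, 12, 14, 16, 16, 20)
  expect_equal(qwk(true, true), 1.0)
  near <- qwk(c(8, 10, 12, 14, 14, 16, 20), true)
  far <- qwk(c(8, 10, 12, 14, 10, 16, 20), true)
  expect_gt(near, far) # 16->14 more acceptable than 16->10
  expect_lte(far, 1)
  expect_warning(qwk(c(12, 12), c(12, 12)), "degenerate")
})

test_that("replicate evaluation reports mean and sd per metric", {
  out <- evaluate_replicates(function(seed) {
    set.seed(seed)
    c(acc = 0.9 + 0.01 * seed, f1 = 0.8)
  }, seeds = 1:5)
  expect_equal(out$metric, c("acc", "f1"))
  expect_equal(out$mean[1], 0.9 + 0.01 * 3)
  expect_equal(out$sd[2], 0)
  expect_equal(out$n, c(5, 5))
})
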
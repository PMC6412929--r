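test_that("identification accuracy is the correct-over-total ratio", {
  expect_equal(identification_accuracy(119, 1)$accuracy, 119 / 120)
  expect_equal(identification_accuracy(0, 7)$accuracy, 0)
  expect_equal(identification_accuracy(7, 0)$accuracy, 1)
  expect_error(identification_accuracy(0, 0), ">= 1")
})

test_that("verification metrics reproduce the balanced 60/60 reference rows", {
  # small-CNN verification row: 60 positives, 60 negatives
  m <- verification_metrics(confusion_counts(tp = 57, fn = 3, tn = 48, fp = 12))
  expect_equal(m$accuracy, 0.8750)
  expect_equal(m$sensitivity, 0.95)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$fpr, 0.20)
  expect_equal(m$fnr, 0.05)
  # near-perfect verifier row
  m2 <- verification_metrics(confusion_counts(tp = 60, fn = 0, tn = 59, fp = 1))
  expect_equal(m2$accuracy, 119 / 120)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 59 / 60)
  expect_equal(m2$fnr, 0)
  # degenerate all-wrong classifier
  m3 <- verification_metrics(confusion_counts(tp = 0, fn = 5, tn = 0, fp = 4))
  expect_equal(m3$sensitivity, 0)
  expect_equal(m3$specificity, 0)
  expect_error(verification_metrics(confusion_counts(0, 5, 0, 0)), "positive")
})

test_that("metric complements hold and match brute-force recomputation", {
  set.seed(14)
  for (i in 1:25) {
    tp <- rpois(1, 20); fn <- rpois(1, 5) + 1
    tn <- rpois(1, 20) + 1; fp <- rpois(1, 5)
    m <- verification_metrics(confusion_counts(tp, tn, fp, fn))
    expect_equal(m$sensitivity + m$fnr, 1)
    expect_equal(m$specificity + m$fpr, 1)
    # brute force from a simulated prediction list
    truth <- c(rep(TRUE, tp + fn), rep(FALSE, tn + fp))
    pred <- c(rep(TRUE, tp), rep(FALSE, fn), rep(FALSE, tn), rep(TRUE, fp))
    expect_equal(m$accuracy, mean(pred == truth))
    expect_equal(m$sensitivity, mean(pred[truth]))
    expect_equal(m$specificity, mean(!pred[!truth]))
  }
})

test_that("roc_curve matches exhaustive threshold enumeration", {
  scores <- c(0.9, 0.4, 0.6, 0.2)
  labels <- c(1, 0, 1, 0)
  roc <- roc_curve(scores, labels)
  ref <- brute_roc(scores, labels)
  ref <- ref[order(-ref[, "threshold"]), ]
  expect_equal(roc$fpr, unname(ref[, "fpr"]))
  expect_equal(roc$tpr, unname(ref[, "tpr"]))
  # perfectly separated scores pass through (0, 1)
  roc2 <- roc_curve(c(5, 4, 1, 0), c(1, 1, 0, 0))
  expect_true(any(roc2$fpr == 0 & roc2$tpr == 1))
  expect_equal(roc_auc(roc2), 1)
  # all-equal scores collapse to the endpoints
  roc3 <- roc_curve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(sort(unique(roc3$fpr)), c(0, 1))
  expect_equal(sort(unique(roc3$tpr)), c(0, 1))
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc and eer agree with brute-force oracles on random score sets", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))    # both classes guaranteed
    scores <- round(rnorm(n, mean = labels), 2) # ties likely
    roc <- roc_curve(scores, labels)
    ref <- brute_roc(scores, labels)
    ref <- ref[order(-ref[, "threshold"]), ]
    expect_equal(roc$fpr, unname(ref[, "fpr"]))
    expect_equal(roc$tpr, unname(ref[, "tpr"]))
    expect_equal(equal_error_rate(roc), brute_eer(scores, labels))
    # cross-check AUC against an independent implementation
    if (i <= 20) {
      auc_ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                       direction = "<")))
      expect_equal(roc_auc(roc), auc_ref, tolerance = 1e-12)
    }
  }
})

test_that("eer endpoints, coin-flip behaviour and interpolation are right", {
  # separable scores -> EER 0
  expect_equal(equal_error_rate(roc_curve(c(3, 2, -1, -2), c(1, 1, 0, 0))), 0)
  # anti-separated -> AUC 0
  expect_equal(roc_auc(roc_curve(c(-1, -2, 3, 2), c(1, 1, 0, 0))), 0)
  # labels independent of scores: EER near 0.5
  set.seed(31)
  n <- 4000
  scores <- rnorm(n)
  labels <- rbinom(n, 1, 0.5)
  expect_equal(equal_error_rate(roc_curve(scores, labels)), 0.5,
               tolerance = 0.05)
  # hand-computed segment-diagonal intersection between
  # (fpr, tpr) = (0.1, 0.8) and (0.3, 0.95)
  pts <- tibble::tibble(threshold = c(2, 1), fpr = c(0.1, 0.3),
                        tpr = c(0.8, 0.95))
  class(pts) <- c("roc_points", class(tibble::tibble()))
  expect_equal(equal_error_rate(pts), 0.1 + (0.1 / 0.35) * 0.2)
})

test_that("eer is invariant under strictly monotone score transforms", {
  set.seed(77)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(0, 1)
  e1 <- equal_error_rate(roc_curve(scores, labels))
  e2 <- equal_error_rate(roc_curve(exp(scores), labels))
  e3 <- equal_error_rate(roc_curve(2 * scores - 5, labels))
  expect_equal(e1, e2)
  expect_equal(e1, e3)
})

test_that("one-against-all datasets are balanced, disjoint and deterministic", {
  beats <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:61), each = 60),
    beat = rep(1:60, 61),
    payload = seq_len(61 * 60)
  )
  oaa <- build_one_against_all(beats, "S01", 60)
  expect_equal(nrow(oaa), 120L)
  expect_equal(sum(oaa$label == "positive"), 60L)
  expect_equal(sum(oaa$label == "negative"), 60L)
  # the positive subject never appears among negatives
  expect_false(any(oaa$subject_id[oaa$label == "negative"] == "S01"))
  # negatives come one from each of 60 distinct subjects
  expect_equal(length(unique(oaa$subject_id[oaa$label == "negative"])), 60L)
  # deterministic: repeated calls give identical selections
  expect_identical(oaa, build_one_against_all(beats, "S01", 60))
  expect_error(build_one_against_all(beats[1:300, ], "S01", 60), "other subjects")
})
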
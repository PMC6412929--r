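#' Identification accuracy from correct/wrong counts
#'
#' Accuracy is the number of correct classifications divided by the total:
#' `cc / (cc + wc)`.
#'
#' @param cc Number of correct classifications (>= 0).
#' @param wc Number of wrong classifications (>= 0); `cc + wc >= 1`.
#' @return One-row tibble with `cc`, `wc`, `accuracy`.
#' @examples
#' identification_accuracy(119, 1)
#' @export
identification_accuracy <- function(cc, wc) {
  cc <- as.integer(cc); wc <- as.integer(wc)
  if (is.na(cc) || is.na(wc) || cc < 0L || wc < 0L || cc + wc < 1L) {
    stop("`cc` and `wc` must be non-negative with cc + wc >= 1", call. = FALSE)
  }
  tibble::tibble(cc = cc, wc = wc, accuracy = cc / (cc + wc))
}

#' Confusion counts for binary verification
#'
#' @param tp,tn,fp,fn Non-negative integer counts; at least one observation in
#'   total, with `tp + fn >= 1` (some positives) and `tn + fp >= 1` (some
#'   negatives) required by [verification_metrics()].
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)) || sum(v) < 1) {
    stop("counts must be non-negative integers with a positive total", call. = FALSE)
  }
  structure(stats::setNames(as.list(as.integer(v)), names(v)),
            class = "confusion_counts")
}

#' Verification metrics from confusion counts
#'
#' The five standard ratios of biometric verification:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, false positive rate `FP/(TN+FP)` and false negative rate
#' `FN/(TP+FN)`. Sensitivity and FNR sum to one, as do specificity and FPR.
#'
#' @param counts A [confusion_counts()] object.
#' @return One-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `fpr`, `fnr` (all in `[0, 1]`).
#' @examples
#' verification_metrics(confusion_counts(tp = 57, tn = 48, fp = 12, fn = 3))
#' @export
verification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    if (tp + fn < 1L) stop("no positive examples (tp + fn = 0)", call. = FALSE)
    if (tn + fp < 1L) stop("no negative examples (tn + fp = 0)", call. = FALSE)
    tibble::tibble(
      accuracy = (tp + tn) / (tp + tn + fp + fn),
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      fpr = fp / (tn + fp),
      fnr = fn / (tp + fn)
    )
  })
}

#' ROC curve from scores and binary labels
#'
#' Sweeps a decision threshold over the score range (midpoints between
#' consecutive distinct scores, plus sentinels below and above all scores)
#' and records one `(fpr, tpr)` point per threshold. Higher scores are more
#' positive; a score equal to the threshold counts as a negative decision
#' (strictly-greater rule), so tied scores move together.
#'
#' @param scores Numeric vector.
#' @param labels Binary labels (logical, 0/1, or a two-level factor where the
#'   second level is positive).
#' @return An object of class `roc_points`: tibble with columns `threshold`,
#'   `fpr`, `tpr`, ordered by decreasing threshold (fpr non-decreasing).
#' @export
roc_curve <- function(scores, labels) {
  scores <- as.numeric(scores)
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("`scores` and `labels` lengths differ", call. = FALSE)
  if (!any(y) || all(y)) stop("labels must contain both classes", call. = FALSE)
  if (!all(is.finite(scores))) stop("`scores` must be finite", call. = FALSE)
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  np <- sum(y); nn <- sum(!y)
  pts <- purrr::map_dfr(thr, function(th) {
    pred <- scores > th
    tibble::tibble(threshold = th,
                   fpr = sum(pred & !y) / nn,
                   tpr = sum(pred & y) / np)
  })
  pts <- dplyr::arrange(pts, dplyr::desc(.data$threshold))
  structure(pts, class = c("roc_points", class(pts)))
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("factor labels must have two levels", call. = FALSE)
    return(labels == levels(labels)[2L])
  }
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (length(lv) != 2L) stop("character labels must have two values", call. = FALSE)
    return(labels == lv[2L])
  }
  stop("cannot interpret `labels` as binary", call. = FALSE)
}

#' Area under an ROC curve (trapezoid rule)
#'
#' @param roc A [roc_curve()] result.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "roc_points"))
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Equal error rate of an ROC curve
#'
#' The operating point where the false positive rate equals the false
#' negative rate (`fnr = 1 - tpr`). The crossing is located by linear
#' interpolation between the two adjacent ROC points that bracket it.
#'
#' @param roc A [roc_curve()] result.
#' @return EER in `[0, 1]`.
#' @examples
#' r <- roc_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' equal_error_rate(r)  # separable scores -> 0
#' @export
equal_error_rate <- function(roc) {
  stopifnot(inherits(roc, "roc_points"))
  # walk in threshold order: fpr increases, fnr decreases
  fpr <- roc$fpr; fnr <- 1 - roc$tpr
  d <- fpr - fnr
  hit <- which(d == 0)
  if (length(hit) > 0) return(fpr[hit[1]])
  k <- which(d[-length(d)] < 0 & d[-1] > 0)
  if (length(k) == 0) {
    # no sign change on the grid: take the point of smallest |fpr - fnr|
    i <- which.min(abs(d))
    return((fpr[i] + fnr[i]) / 2)
  }
  i <- k[1]
  # linear interpolation of (fpr, fnr) between points i and i+1
  t <- -d[i] / (d[i + 1] - d[i])
  fpr[i] + t * (fpr[i + 1] - fpr[i])
}

#' @export
print.roc_points <- function(x, ...) {
  cat(sprintf("<roc_points> %d thresholds, AUC %.4f, EER %.4f\n",
              nrow(x), roc_auc(x), equal_error_rate(x)))
  invisible(x)
}

#' ROC plot
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @export
autoplot.roc_points <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
}

#' Build a one-against-all verification dataset
#'
#' Recasts a multi-subject dataset as a balanced binary problem: the positive
#' class is `samples_per_person` items of the chosen subject; the negative
#' class takes the first item from each of `samples_per_person` distinct
#' other subjects (in sorted subject order, deterministic).
#'
#' @param data Data frame with a `subject_id` column; other columns ride
#'   along.
#' @param positive_subject Subject label of the positive class.
#' @param samples_per_person Items per class (default 60).
#' @return Tibble: the input rows selected, plus a `label` column with values
#'   `"negative"`/`"positive"` (positive is the second factor level used by
#'   [roc_curve()]).
#' @export
build_one_against_all <- function(data, positive_subject, samples_per_person = 60L) {
  if (!is.data.frame(data) || !"subject_id" %in% names(data)) {
    stop("`data` must have a `subject_id` column", call. = FALSE)
  }
  samples_per_person <- as.integer(samples_per_person)
  data <- tibble::as_tibble(data)
  pos_rows <- which(data$subject_id == positive_subject)
  if (length(pos_rows) < samples_per_person) {
    stop("positive subject has too few items", call. = FALSE)
  }
  others <- sort(unique(data$subject_id[data$subject_id != positive_subject]))
  if (length(others) < samples_per_person) {
    stop("not enough other subjects for the negative class", call. = FALSE)
  }
  others <- others[seq_len(samples_per_person)]
  neg_rows <- vapply(others, function(s) which(data$subject_id == s)[1L], integer(1))
  out <- dplyr::bind_rows(
    dplyr::mutate(data[pos_rows[seq_len(samples_per_person)], ], label = "positive"),
    dplyr::mutate(data[neg_rows, ], label = "negative")
  )
  out
}
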
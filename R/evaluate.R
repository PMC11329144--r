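#' Construct a confusion matrix
#'
#' Abnormal (stenotic) is the positive class throughout.
#'
#' @param TP,FP,FN,TN Non-negative counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FP, FN, TN) {
  v <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(v < 0) || any(v != round(v))) stop("confusion_matrix: counts must be non-negative integers")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("abnormal", "normal"),
                              predicted = c("abnormal", "normal")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2PR/(P+R)`, and (when scores are supplied) AUC by
#' trapezoidal integration of the ROC curve. A ratio with zero denominator is
#' reported as `NaN` with a warning, never silently as 0.
#'
#' @param cm A [confusion_matrix()].
#' @param scores Optional data frame / list with elements `score` (abnormal
#'   score in \[0, 1\]) and `label` (1 = abnormal, 0 = normal), required for AUC.
#' @return An object of class `metrics_report`: accuracy, precision, recall,
#'   f1, auc (NA if no scores), and the confusion matrix.
#' @export
compute_metrics <- function(cm, scores = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("compute_metrics: ", what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  accuracy <- safe_div(cm$TP + cm$TN, total, "accuracy")
  precision <- safe_div(cm$TP, cm$TP + cm$FP, "precision")
  recall <- safe_div(cm$TP, cm$TP + cm$FN, "recall")
  f1 <- if (is.nan(precision) || is.nan(recall)) NaN
        else safe_div(2 * precision * recall, precision + recall, "F1")
  auc <- if (!is.null(scores)) auc_roc(scores$score, scores$label) else NA_real_
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, auc = auc, confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f  AUC %s\n",
              round_half_up(x$accuracy), round_half_up(x$precision),
              round_half_up(x$recall), round_half_up(x$f1),
              if (is.na(x$auc)) "-" else sprintf("%.4f", round_half_up(x$auc))))
  invisible(x)
}

#' ROC curve points
#'
#' Thresholds sweep the unique scores from high to low; tied scores move as a
#' group, so the curve's diagonal segments give tied pairs half credit.
#'
#' @param score Numeric scores (higher = more abnormal).
#' @param label 0/1 (or logical) truth, 1 = abnormal.
#' @return Data frame with columns `fpr`, `tpr` from (0, 0) to (1, 1).
#' @export
roc_points <- function(score, label) {
  label <- as.integer(label)
  if (length(unique(label)) < 2) stop("roc_points: both classes required")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- label[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)          # end of each tie group
  data.frame(fpr = c(0, fp[last] / sum(1 - label)),
             tpr = c(0, tp[last] / sum(label)))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of [roc_points()]; equal to the Mann-Whitney
#' pair statistic (fraction of abnormal-normal pairs correctly ordered, ties
#' counting one half).
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(score, label) {
  pts <- roc_points(score, label)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

#' Stratified k-fold assignment
#'
#' Each class is shuffled (seeded) and dealt round-robin to folds starting at
#' a random offset, so every fold's class proportion is within one recording
#' of the global proportion and the folds partition the data.
#'
#' @param labels Factor/character vector of class labels (or a data frame with
#'   a `label` column).
#' @param k Number of folds (default 5); every class must have at least `k`
#'   members.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, same length as `labels`.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop("stratified_folds: class '", names(tab)[which.min(tab)],
         "' has fewer than k = ", k, " recordings")
  fold <- integer(n)
  with_seed(seed, {
    for (cl in names(tab)) {
      ids <- sample(which(labels == cl))
      offset <- sample.int(k, 1) - 1L
      fold[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
    }
  })
  fold
}

# does the exact ratio x render as the printed 4-dp value (half-up rounding),
# or as its truncation (printed tables occasionally truncate)?
renders_as <- function(x, printed, digits = 4) {
  isTRUE(all.equal(round_half_up(x, digits), printed, tolerance = 1e-9)) ||
    isTRUE(all.equal(floor(x * 10^digits + 1e-9) / 10^digits, printed,
                     tolerance = 1e-9))
}

#' Reconstruct integer confusion matrices from printed metrics
#'
#' Exhaustive search over `TP in 0..n_pos`, `FP in 0..n_neg` for all integer
#' confusion matrices whose accuracy, precision and recall render (4 decimal
#' places, half-up, truncation also accepted) as the printed values. Published
#' tables print only the rounded metrics; on a test set of known class sizes
#' the underlying counts are usually uniquely recoverable, which turns a
#' printed row into an auditable object. Zero matches means the printed row is
#' internally inconsistent and is an error.
#'
#' @param accuracy,precision,recall Printed 4-decimal values.
#' @param n_pos,n_neg Positive (abnormal) and negative class sizes.
#' @return An object of class `confusion_audit`: `matches` (list of
#'   [confusion_matrix()]), `unique` (logical), and `metrics` of the first
#'   match. Errors with "inconsistent printed row" when nothing matches;
#'   warns when the reconstruction is not unique.
#' @export
reconstruct_confusion <- function(accuracy, precision, recall, n_pos, n_neg) {
  stopifnot(n_pos > 0, n_neg > 0)
  total <- n_pos + n_neg
  matches <- list()
  for (TP in 0:n_pos) {
    rec <- TP / n_pos
    if (!renders_as(rec, recall)) next
    for (FP in 0:n_neg) {
      TN <- n_neg - FP
      FN <- n_pos - TP
      if (!renders_as((TP + TN) / total, accuracy)) next
      if (TP + FP == 0) next
      if (!renders_as(TP / (TP + FP), precision)) next
      matches[[length(matches) + 1]] <- confusion_matrix(TP, FP, FN, TN)
    }
  }
  if (length(matches) == 0)
    stop("reconstruct_confusion: inconsistent printed row (no integer counts ",
         "on ", n_pos, " positives / ", n_neg, " negatives reproduce ",
         "accuracy ", accuracy, ", precision ", precision, ", recall ", recall, ")")
  if (length(matches) > 1)
    warning("reconstruct_confusion: ", length(matches),
            " matrices match the printed row; reconstruction is not unique")
  structure(list(matches = matches, unique = length(matches) == 1,
                 metrics = suppressWarnings(compute_metrics(matches[[1]]))),
            class = "confusion_audit")
}

#' @export
print.confusion_audit <- function(x, ...) {
  cat(sprintf("confusion audit: %d matching matrix(es)%s\n", length(x$matches),
              if (x$unique) " (unique)" else ""))
  for (m in x$matches) print(m)
  invisible(x)
}

#' Exact McNemar test on paired per-recording correctness
#'
#' Compares two classifiers evaluated on the same recordings via the exact
#' binomial distribution of the discordant pairs. With no discordant pairs
#' (e.g. identical predictions) the p-value is 1.
#'
#' @param correct_a,correct_b Logical vectors: was each recording classified
#'   correctly by arm A / arm B?
#' @return List with `p_value`, `b` (A right, B wrong), `c` (A wrong, B right).
#' @export
mcnemar_paired <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  p <- if (b + cc == 0) 1 else stats::binom.test(b, b + cc, 0.5)$p.value
  list(p_value = p, b = b, c = cc)
}
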
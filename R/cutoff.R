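# ROC / Youden-index machinery used to set the polysomy-vs-normal
# copy-number cutoff.

split_classes <- function(values, labels, positive = NULL) {
  stopifnot(length(values) == length(labels))
  if (is.logical(labels)) {
    pos <- values[labels]
    neg <- values[!labels]
  } else {
    if (is.null(positive)) {
      lv <- unique(as.character(labels))
      if (length(lv) != 2) {
        stop_validation("labels must have exactly two levels or 'positive' must be given")
      }
      positive <- if ("polysomy" %in% lv) "polysomy" else lv[1]
    }
    pos <- values[as.character(labels) == positive]
    neg <- values[as.character(labels) != positive]
  }
  if (length(pos) == 0 || length(neg) == 0) {
    stop_validation("both classes must be non-empty")
  }
  list(pos = pos, neg = neg)
}

auc_rank <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve and Youden-optimal cutoff
#'
#' Builds the ROC curve of a continuous marker (here: MET copy number)
#' against binary labels, with positives expected at higher values. A
#' sample is called positive when its value is at or above the threshold.
#' Candidate thresholds are midpoints between consecutive sorted unique
#' values, plus one sentinel below and one above all values. The AUC is
#' the Mann-Whitney rank statistic (ties count half). The reported cutoff
#' maximises the Youden index J = sensitivity + specificity - 1; among
#' tied maxima the smallest threshold is returned (maximising sensitivity
#' at equal J).
#'
#' @param values Numeric marker values.
#' @param labels Logical vector (`TRUE` = positive) or a two-level label
#'   vector.
#' @param positive Positive label when `labels` is not logical; defaults
#'   to `"polysomy"` when present, otherwise the first level.
#' @return Object of class `roc_cutoff`: `points` (threshold, sensitivity,
#'   specificity, youden), `auc`, `best_threshold`, `best_j`, and counts
#'   `n_pos`, `n_neg`.
#' @export
roc_curve <- function(values, labels, positive = NULL) {
  cl <- split_classes(values, labels, positive)
  u <- sort(unique(c(cl$pos, cl$neg)))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
           u[length(u)] + 1)
  sens <- vapply(thr, function(t) mean(cl$pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(cl$neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # thresholds ascend: smallest wins
  structure(
    list(points = data.frame(threshold = thr, sensitivity = sens,
                             specificity = spec, youden = j),
         auc = auc_rank(cl$pos, cl$neg),
         best_threshold = thr[best], best_j = j[best],
         n_pos = length(cl$pos), n_neg = length(cl$neg)),
    class = "roc_cutoff"
  )
}

#' Youden index
#'
#' `J = sensitivity + specificity - 1`.
#'
#' @param sensitivity,specificity Fractions in `[0, 1]`.
#' @return Numeric J.
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    stop_validation("sensitivity and specificity must lie in [0, 1]")
  }
  sensitivity + specificity - 1
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Stratified resampling (within each class) with percentile 2.5/97.5
#' bounds. Deterministic under a fixed seed.
#'
#' @param values,labels,positive As in [roc_curve()].
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(low, high)` with the bootstrap AUCs attached
#'   as attribute `"aucs"`.
#' @export
bootstrap_auc_ci <- function(values, labels, n_boot = 2000, seed = NULL,
                             conf = 0.95, positive = NULL) {
  cl <- split_classes(values, labels, positive)
  if (length(cl$pos) < 2 || length(cl$neg) < 2) {
    stop_validation("each class needs >= 2 members for a bootstrap CI")
  }
  if (!is.null(seed)) set.seed(seed)
  aucs <- vapply(seq_len(n_boot), function(i) {
    auc_rank(sample(cl$pos, replace = TRUE), sample(cl$neg, replace = TRUE))
  }, numeric(1))
  q <- stats::quantile(aucs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  structure(c(low = q[1], high = q[2]), aucs = aucs)
}

#' @export
print.roc_cutoff <- function(x, ...) {
  cat(sprintf("ROC over %d positives / %d negatives\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f; best cutoff %.4g (value >= cutoff is positive)\n",
              x$auc, x$best_threshold))
  i <- which(x$points$threshold == x$best_threshold)[1]
  cat(sprintf("  at cutoff: sensitivity %.3f, specificity %.3f, J = %.3f\n",
              x$points$sensitivity[i], x$points$specificity[i], x$best_j))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x A `roc_cutoff`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_cutoff <- function(x, ...) {
  o <- order(1 - x$points$specificity, x$points$sensitivity)
  graphics::plot(1 - x$points$specificity[o], x$points$sensitivity[o],
                 type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  i <- which(x$points$threshold == x$best_threshold)[1]
  graphics::points(1 - x$points$specificity[i], x$points$sensitivity[i],
                   pch = 19, col = "firebrick")
  invisible(x)
}
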
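# Diagnostic-agreement statistics: confusion matrices against a reference
# method, one-vs-rest class metrics, Cohen's kappa, MSAF, and the
# MSAF-stratified tissue-plasma percent-agreement analysis.

#' Build a confusion matrix against a reference
#'
#' Rows are the test method, columns the reference (truth) method —
#' `counts[i, j]` is the number of pairs with test label `classes[i]` and
#' reference label `classes[j]`.
#'
#' @param reference Reference labels.
#' @param test Test labels (same length).
#' @param classes Ordered class labels; defaults to the sorted union.
#' @return Object of class `confusion_matrix` with `classes` and `counts`.
#' @export
confusion <- function(reference, test, classes = NULL) {
  if (length(reference) == 0) stop_validation("no pairs supplied")
  stopifnot(length(reference) == length(test))
  reference <- as.character(reference)
  test <- as.character(test)
  classes <- classes %||% sort(unique(c(reference, test)))
  bad <- setdiff(unique(c(reference, test)), classes)
  if (length(bad)) {
    stop_validation(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  }
  counts <- table(factor(test, levels = classes),
                  factor(reference, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(test = classes, reference = classes))
  structure(list(classes = classes, counts = counts),
            class = "confusion_matrix")
}

#' Construct a confusion matrix directly from counts
#'
#' @param counts Square integer matrix, rows = test, columns = reference.
#' @param classes Class labels in matrix order.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(counts, classes) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(classes), ncol(counts) == length(classes),
            all(counts >= 0))
  if (sum(counts) == 0) stop_validation("confusion matrix has zero total")
  dimnames(counts) <- list(test = classes, reference = classes)
  structure(list(classes = classes, counts = counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = test, columns = reference)\n")
  print(x$counts)
  invisible(x)
}

#' Expand a confusion matrix into its pair list
#'
#' Inverse of [confusion()]: one `(reference, test)` row per counted pair.
#'
#' @param m A `confusion_matrix`.
#' @return A `data.frame` with columns `reference`, `test`.
#' @export
confusion_pairs <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  idx <- which(m$counts > 0, arr.ind = TRUE)
  ref <- rep(m$classes[idx[, 2]], m$counts[idx])
  tst <- rep(m$classes[idx[, 1]], m$counts[idx])
  data.frame(reference = ref, test = tst, stringsAsFactors = FALSE)
}

#' One-vs-rest diagnostic metrics for one class
#'
#' Collapses the matrix to `cls` vs rest with the reference as truth and
#' reports sensitivity, specificity, positive and negative predictive
#' value, and overall agreement `(TP + TN) / N`. Metrics whose denominator
#' is zero are `NA` ("undefined"), never silently 0.
#'
#' @param m A `confusion_matrix`.
#' @param cls Class to collapse on.
#' @return Object of class `class_metrics` with the four counts and the
#'   five metrics (fractions).
#' @export
class_metrics <- function(m, cls) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (!cls %in% m$classes) stop_validation(paste0("unknown class: ", cls))
  total <- sum(m$counts)
  tp <- m$counts[cls, cls]
  fp <- sum(m$counts[cls, ]) - tp
  fn <- sum(m$counts[, cls]) - tp
  tn <- total - tp - fp - fn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(class = cls, tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         ppv = ratio(tp, tp + fp),
         npv = ratio(tn, tn + fn),
         agreement = (tp + tn) / total),
    class = "class_metrics"
  )
}

#' @export
print.class_metrics <- function(x, ...) {
  fmt <- function(v, d = 1) if (is.na(v)) "undefined" else paste0(as_percent(v, d), "%")
  cat(sprintf("Class '%s' vs rest (reference as truth)\n", x$class))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %s  specificity %s  agreement %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$agreement)))
  cat(sprintf("  PPV %s  NPV %s\n", fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Round a fraction to a displayed percentage
#'
#' Round-half-up at the requested number of decimals (one decimal for
#' tissue concordance metrics, nearest percent for the stratified plasma
#' metrics).
#'
#' @param x Fraction in `[0, 1]` (or `NA`).
#' @param digits Decimal places of the percentage (default 1).
#' @return Numeric percentage.
#' @export
as_percent <- function(x, digits = 1) {
  s <- 10^digits
  ifelse(is.na(x), NA_real_, floor(x * 100 * s + 0.5 + 1e-9) / s)
}

#' Cohen's kappa of a confusion matrix
#'
#' Unweighted kappa, `(Po - Pe) / (1 - Pe)` with observed agreement
#' `Po = diagonal / N` and chance agreement
#' `Pe = sum(row_i * col_i) / N^2`.
#'
#' @param m A `confusion_matrix`.
#' @return Numeric kappa.
#' @export
cohen_kappa <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  n <- sum(m$counts)
  if (n == 0) stop_validation("empty confusion matrix")
  po <- sum(diag(m$counts)) / n
  pe <- sum(rowSums(m$counts) * colSums(m$counts)) / n^2
  if (pe >= 1) stop_validation("degenerate marginals: chance agreement is 1")
  (po - pe) / (1 - pe)
}

#' Maximum somatic allele frequency
#'
#' The largest variant allele fraction among a sample's somatic variants;
#' a proxy for ctDNA content. An empty list yields 0 by convention.
#'
#' @param vafs Numeric vector of somatic variant allele fractions.
#' @return Fraction in `[0, 1]`.
#' @export
msaf <- function(vafs) {
  if (length(vafs) == 0) return(0)
  if (any(vafs < 0 | vafs > 1, na.rm = TRUE)) {
    stop_validation("variant allele fractions must lie in [0, 1]")
  }
  max(vafs, na.rm = TRUE)
}

#' Stratified positive/negative percent agreement
#'
#' Within the subset of paired samples passing `filter`, computes, for
#' `target_status`, the positive percent agreement (plasma positive among
#' tissue positive) and negative percent agreement (plasma negative among
#' tissue negative), treating the tissue call as comparator. Metrics with
#' a zero denominator are `NA`.
#'
#' @param pairs `data.frame` of paired samples (see
#'   [read_paired_samples()]).
#' @param target_status Status defining "positive".
#' @param filter `NULL` (vacuous), or a function `pairs -> logical`
#'   selecting the subset (e.g. `function(d) d$msaf_plasma > 0.05`).
#' @return List with `ppa`, `npa`, `n_selected`.
#' @export
stratified_agreement <- function(pairs, target_status, filter = NULL) {
  stopifnot(target_status %in% met_statuses())
  sel <- if (is.null(filter)) rep(TRUE, nrow(pairs)) else filter(pairs)
  sel[is.na(sel)] <- FALSE
  d <- pairs[sel, , drop = FALSE]
  if (nrow(d) == 0) return(list(ppa = NA_real_, npa = NA_real_, n_selected = 0L))
  tpos <- d$tissue_status == target_status
  ppos <- d$plasma_status == target_status
  list(
    ppa = if (any(tpos)) mean(ppos[tpos]) else NA_real_,
    npa = if (any(!tpos)) mean(!ppos[!tpos]) else NA_real_,
    n_selected = nrow(d)
  )
}

#' Status prevalence in a cohort of calls
#'
#' @param calls Character vector of statuses, or a list of `met_call`
#'   objects.
#' @return Named numeric vector of fractions over [met_statuses()],
#'   summing to 1.
#' @export
cohort_prevalence <- function(calls) {
  if (length(calls) == 0) stop_validation("no calls supplied")
  statuses <- if (is.character(calls)) {
    calls
  } else {
    vapply(calls, function(c) c$status, character(1))
  }
  bad <- setdiff(unique(statuses), met_statuses())
  if (length(bad)) {
    stop_validation(paste0("unknown status: ", paste(bad, collapse = ", ")))
  }
  tab <- table(factor(statuses, levels = met_statuses()))
  p <- as.numeric(tab) / length(statuses)
  names(p) <- met_statuses()
  p
}
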
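#' Per-label voxel counts and volumes
#'
#' Counts the voxels of every tissue label (labels `> 0`; 0 is the
#' background sentinel) and converts counts to physical volume,
#' `volume = count * prod(voxel_size)` in cubic millimetres.
#'
#' @param labels Integer label array (e.g. from [defuzzify()] or a
#'   phantom's ground truth).
#' @param voxel_size Voxel extent per axis, mm.
#' @param n_labels Number of label classes to report (default: the maximum
#'   label present); classes absent from the map get count 0.
#' @return A data frame with columns `label`, `count`, `volume_mm3`.
#' @export
label_volumes <- function(labels, voxel_size = c(1, 1, 1),
                          n_labels = NULL) {
  lab <- as.integer(labels[labels > 0])
  if (is.null(n_labels)) n_labels <- if (length(lab)) max(lab) else 0L
  counts <- tabulate(lab, nbins = n_labels)
  vox <- prod(voxel_size)
  data.frame(label = seq_len(n_labels),
             count = counts,
             volume_mm3 = counts * vox)
}

#' Match predicted cluster labels to ground truth
#'
#' Cluster labels are arbitrary; before any voxel-wise comparison the
#' predicted labels are permuted to maximize the total overlap with the
#' reference labeling (exact optimal assignment over the contingency
#' table, found by exhaustive permutation search; deterministic, first
#' optimum in lexicographic order).  Differing label counts are handled by
#' padding the table with empty classes.
#'
#' @param pred,truth Integer label arrays of the same shape; 0 marks
#'   out-of-mask voxels and is never remapped.
#' @return `pred` relabeled into the reference label space.
#' @export
match_labels <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    ik_stop("label maps must share a shape", "data")
  }
  m <- pred > 0 & truth > 0
  K <- max(max(pred), max(truth))
  if (K > 8) ik_stop("label matching supports up to 8 classes", "usage")
  tab <- table(factor(pred[m], levels = seq_len(K)),
               factor(truth[m], levels = seq_len(K)))
  best <- NULL
  best_score <- -1
  for (p in all_permutations(K)) {
    sc <- sum(tab[cbind(seq_len(K), p)])
    if (sc > best_score) {
      best_score <- sc
      best <- p
    }
  }
  out <- pred
  pos <- pred > 0
  out[pos] <- best[pred[pos]]
  out
}

# All permutations of 1..k, lexicographic order.
all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (i in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = i - 1L)
    }
  }
  # regenerate in lexicographic order of the first element
  out[order(vapply(out, function(p) sum(p * k^rev(seq_len(k))), numeric(1)))]
}

#' Confusion-matrix metrics for one label (one-vs-rest)
#'
#' Exact confusion counts over the evaluated voxels (those with a
#' non-sentinel reference label) for the given positive class, and the
#' derived rates: accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and Dice `2TP/(2TP+FP+FN)`.
#'
#' @param pred,truth Integer label arrays (labels already matched, see
#'   [match_labels()]).
#' @param positive The label treated as the positive class.
#' @return A `confusion_metrics` list with integer counts `tp`, `fp`,
#'   `tn`, `fn` and the four rates.
#' @export
binary_metrics <- function(pred, truth, positive) {
  if (!identical(dim(pred), dim(truth))) {
    ik_stop("label maps must share a shape", "data")
  }
  m <- truth > 0
  p <- pred[m] == positive
  t <- truth[m] == positive
  tp <- sum(p & t); fp <- sum(p & !t)
  fn <- sum(!p & t); tn <- sum(!p & !t)
  sens <- if (tp + fn == 0) {
    warning("no positive voxels in reference; sensitivity undefined")
    NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) NaN else tn / (tn + fp)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / (tp + tn + fp + fn),
         sensitivity = sens,
         specificity = spec,
         dice = if (2 * tp + fp + fn == 0) NaN else
           2 * tp / (2 * tp + fp + fn)),
    class = "confusion_metrics"
  )
}

#' Overall voxel accuracy of a segmentation
#'
#' Fraction of evaluated voxels (non-sentinel reference label) whose
#' predicted label equals the reference, after optimal label matching.
#'
#' @inheritParams binary_metrics
#' @param match Run [match_labels()] first (default `TRUE`).
#' @return Scalar accuracy in `[0, 1]`.
#' @export
segmentation_accuracy <- function(pred, truth, match = TRUE) {
  if (match) pred <- match_labels(pred, truth)
  m <- truth > 0
  mean(pred[m] == truth[m])
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("<confusion_metrics> tp=", x$tp, " fp=", x$fp, " tn=", x$tn,
      " fn=", x$fn, "\n  accuracy=", format(x$accuracy, digits = 4),
      " sensitivity=", format(x$sensitivity, digits = 4),
      " specificity=", format(x$specificity, digits = 4),
      " dice=", format(x$dice, digits = 4), "\n", sep = "")
  invisible(x)
}
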
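#' Classification metrics from confusion counts
#'
#' The positive class is the incorrect trial. F1 is the harmonic mean of
#' sensitivity (TP/(TP+FN)) and precision (TP/(TP+FP)), defined as 0 when
#' precision + sensitivity is 0. Specificity (and hence balanced accuracy,
#' the mean of sensitivity and specificity) is `NA` when TN + FP = 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (at least one positive).
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `precision`,
#'   `sensitivity`, `specificity`, `accuracy`, `balanced_accuracy`, `f1`.
#' @examples
#' compute_metrics(9, 1, 7, 3)
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0) || tp + fp + tn + fn < 1) {
    abort("counts must be non-negative with at least one observation")
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + fp + tn + fn)
  bacc <- if (is.na(spec) || is.na(sens)) NA_real_ else (sens + spec) / 2
  f1 <- if (is.na(sens) || prec + sens == 0) 0 else
    2 * prec * sens / (prec + sens)
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn, precision = prec,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 balanced_accuracy = bacc, f1 = f1)
}

#' F1 of the all-positive detector
#'
#' The floor any useful classifier must beat on unbalanced data: labelling
#' every trial incorrect gives sensitivity 1 and precision P/(P+N), hence
#' F1 = 2P/(2P+N) for P incorrect and N correct trials.
#'
#' @param n_incorrect,n_correct Trial counts (P and N).
#' @return F1 in (0, 1].
#' @examples
#' all_positive_baseline(518, 202) # ~0.84
#' @export
all_positive_baseline <- function(n_incorrect, n_correct) {
  if (n_incorrect < 1) abort("need at least one incorrect (positive) trial")
  2 * n_incorrect / (2 * n_incorrect + n_correct)
}
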
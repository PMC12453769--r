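# Evaluation suite: confusion-table metrics (precision, recall, F1,
# specificity, NPV, accuracy), Cohen's kappa in two chance-term variants,
# per-class one-vs-rest reports, and Dice / IoU overlap scores.

#' Construct a binary confusion table
#'
#' @param TP,TN,FP,FN Non-negative counts.
#' @return list with the four counts and the total `T_obs`.
#' @export
confusion_table <- function(TP, TN, FP, FN) {
  cts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(cts < 0)) stop_invalid("confusion counts must be non-negative")
  tot <- sum(cts)
  if (tot == 0) stop_invalid("confusion table is empty")
  list(TP = TP, TN = TN, FP = FP, FN = FN, T_obs = tot)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary classification metrics from a confusion table
#'
#' precision = TP/(TP+FP); recall = TP/(TP+FN); F1 = harmonic mean of
#' the two; specificity = TN/(TN+FP); NPV = TN/(TN+FN);
#' accuracy = (TP+TN)/T_obs.  Metrics with a zero denominator are
#' reported as NA (undefined, never silently 0) and listed in the
#' `undefined` attribute.
#'
#' @param ct Confusion table from [confusion_table()].
#' @return Named list of the six metrics; attribute `undefined` names any
#'   metric whose denominator was zero.
#' @export
binary_metrics <- function(ct) {
  prec <- safe_ratio(ct$TP, ct$TP + ct$FP)
  rec <- safe_ratio(ct$TP, ct$TP + ct$FN)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  out <- list(
    precision = prec,
    recall = rec,
    f1 = f1,
    specificity = safe_ratio(ct$TN, ct$TN + ct$FP),
    npv = safe_ratio(ct$TN, ct$TN + ct$FN),
    accuracy = (ct$TP + ct$TN) / ct$T_obs
  )
  und <- names(out)[vapply(out, is.na, logical(1))]
  if (length(und)) {
    warning("undefined metrics (zero denominator): ",
            paste(und, collapse = ", "), call. = FALSE)
  }
  attr(out, "undefined") <- und
  out
}

#' Cohen's kappa, printed-form chance term
#'
#' kappa = (P(a) - P(e)) / (1 - P(e)) with P(a) = (TP+TN)/T_obs and the
#' chance-agreement term P(e) = (TP*TN + FP*FN)/T_obs^2.  Note this
#' chance term differs from the conventional product-of-marginals form,
#' which [kappa_standard()] provides.
#'
#' @param ct Confusion table.
#' @return Kappa value; NA if P(e) = 1.
#' @export
kappa_paper <- function(ct) {
  pa <- (ct$TP + ct$TN) / ct$T_obs
  pe <- (ct$TP * ct$TN + ct$FP * ct$FN) / ct$T_obs^2
  if (pe == 1) return(NA_real_)
  (pa - pe) / (1 - pe)
}

#' Cohen's kappa, conventional chance term
#'
#' P(e) = [(TP+FP)(TP+FN) + (TN+FN)(TN+FP)] / T_obs^2 (product of
#' marginals for each category).
#'
#' @param ct Confusion table.
#' @return Kappa value; NA if P(e) = 1.
#' @export
kappa_standard <- function(ct) {
  pa <- (ct$TP + ct$TN) / ct$T_obs
  pe <- ((ct$TP + ct$FP) * (ct$TP + ct$FN) +
           (ct$TN + ct$FN) * (ct$TN + ct$FP)) / ct$T_obs^2
  if (pe == 1) return(NA_real_)
  (pa - pe) / (1 - pe)
}

#' Multi-class confusion matrix from labels
#'
#' @param truth,pred Factors or vectors of class labels.
#' @param classes Class order (default the four smear classes).
#' @return K x K count matrix, rows = truth, columns = prediction.
#' @export
multiclass_confusion <- function(truth, pred,
                                 classes = smear_classes()) {
  t <- factor(truth, levels = classes)
  p <- factor(pred, levels = classes)
  unclass(table(truth = t, pred = p))
}

#' One-vs-rest collapse of a multi-class confusion matrix
#'
#' @param mc K x K count matrix.
#' @param class Class name or index to treat as positive.
#' @return A binary [confusion_table()].
#' @export
collapse_ovr <- function(mc, class) {
  if (is.character(class)) class <- match(class, rownames(mc))
  TP <- mc[class, class]
  FN <- sum(mc[class, ]) - TP
  FP <- sum(mc[, class]) - TP
  TN <- sum(mc) - TP - FN - FP
  confusion_table(TP, TN, FP, FN)
}

#' Per-class metrics and overall accuracy for a multi-class confusion
#'
#' Each class is collapsed one-vs-rest to a binary confusion table and
#' scored with [binary_metrics()]; overall accuracy is trace/total.
#'
#' @param mc K x K count matrix with class dimnames.
#' @return list(per_class = named list of metric lists,
#'   overall_accuracy = scalar).
#' @export
multiclass_report <- function(mc) {
  if (sum(mc) == 0) stop_invalid("confusion matrix is all zero")
  cls <- rownames(mc) %||% as.character(seq_len(nrow(mc)))
  per <- lapply(seq_len(nrow(mc)), function(k)
    suppressWarnings(binary_metrics(collapse_ovr(mc, k))))
  names(per) <- cls
  list(per_class = per, overall_accuracy = sum(diag(mc)) / sum(mc))
}

check_masks <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop_invalid("mask shapes differ")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop_invalid("masks must be binary")
}

#' Dice similarity coefficient
#'
#' DSC = 2|A intersect B| / (|A| + |B|).  When both masks are empty the
#' score is 1 by convention (perfect agreement on absence); set
#' `both_empty = NA` to report undefined instead.
#'
#' @param mask_a,mask_b Binary masks of equal shape.
#' @param both_empty Value returned when both masks are empty.
#' @return DSC in [0, 1].
#' @export
dsc <- function(mask_a, mask_b, both_empty = 1) {
  check_masks(mask_a, mask_b)
  s <- sum(mask_a) + sum(mask_b)
  if (s == 0) return(both_empty)
  2 * sum(mask_a * mask_b) / s
}

#' Jaccard index (intersection over union)
#'
#' IoU = |A intersect B| / |A union B|; related to Dice by
#' DSC = 2 IoU / (1 + IoU).
#'
#' @inheritParams dsc
#' @return IoU in [0, 1].
#' @export
iou <- function(mask_a, mask_b, both_empty = 1) {
  check_masks(mask_a, mask_b)
  inter <- sum(mask_a * mask_b)
  un <- sum(mask_a) + sum(mask_b) - inter
  if (un == 0) return(both_empty)
  inter / un
}

#' Threshold a probability map to a binary mask
#'
#' Pixel = 1 iff p >= threshold (ties go to foreground).
#'
#' @param probabilities Values in [0, 1].
#' @param threshold Cut point in [0, 1] (default 0.5).
#' @return Binary mask of the same shape.
#' @export
prob_to_mask <- function(probabilities, threshold = 0.5) {
  if (threshold < 0 || threshold > 1)
    stop_invalid("threshold must lie in [0, 1]")
  if (any(probabilities < 0 | probabilities > 1))
    stop_invalid("probabilities must lie in [0, 1]")
  m <- (probabilities >= threshold) * 1
  if (!is.null(dim(probabilities))) dim(m) <- dim(probabilities)
  m
}
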
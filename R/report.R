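# Evaluation reports: per-task metric bundles in the JSON/CSV schema
# shared by the command-line tools.

#' Evaluate a model on a set of samples
#'
#' Classification tasks are scored with the 4-class confusion matrix,
#' per-class one-vs-rest metrics, overall accuracy, and Cohen's kappa on
#' the benign-vs-malignant collapse (both chance-term variants).
#' Segmentation tasks are scored with pixel-level confusion metrics and
#' mean Dice / IoU over samples.  Undefined metrics are reported as NA
#' (serialized as JSON null), never as 0.
#'
#' @param model A ttc_model.
#' @param samples List of SmearSample with labels and masks.
#' @param split Split name recorded in the report.
#' @param threshold Mask binarization threshold.
#' @param batch_size Forward batch size.
#' @return Named list of per-task report lists.
#' @export
evaluate_model <- function(model, samples, split = "test", threshold = 0.5,
                           batch_size = 32L) {
  if (length(samples) == 0) stop_invalid("no samples in split '%s'", split)
  ids <- names(model$task_specs)
  cls <- smear_classes()
  acc <- list()
  nb <- ceiling(length(samples) / batch_size)
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, length(samples))
    bt <- samples_to_batch(samples[idx], model$task_specs)
    pr <- forward_full(model, bt$x, training = FALSE)$preds
    for (id in ids) {
      sp <- model$task_specs[[id]]
      if (sp$kind == "classification") {
        acc[[id]]$pred <- c(acc[[id]]$pred,
                            cls[max.col(pr[[id]], ties.method = "first")])
        acc[[id]]$true <- c(acc[[id]]$true,
                            vapply(samples[idx], `[[`, "", "label"))
      } else {
        for (j in seq_along(idx)) {
          pm <- prob_to_mask(pr[[id]][, , j], threshold)
          tm <- samples[[idx[j]]]$mask
          acc[[id]]$dsc <- c(acc[[id]]$dsc, dsc(pm, tm))
          acc[[id]]$iou <- c(acc[[id]]$iou, iou(pm, tm))
          acc[[id]]$TP <- (acc[[id]]$TP %||% 0) + sum(pm * tm)
          acc[[id]]$FP <- (acc[[id]]$FP %||% 0) + sum(pm * (1 - tm))
          acc[[id]]$FN <- (acc[[id]]$FN %||% 0) + sum((1 - pm) * tm)
          acc[[id]]$TN <- (acc[[id]]$TN %||% 0) + sum((1 - pm) * (1 - tm))
        }
      }
    }
  }
  reports <- list()
  for (id in ids) {
    sp <- model$task_specs[[id]]
    if (sp$kind == "classification") {
      mc <- multiclass_confusion(acc[[id]]$true, acc[[id]]$pred, cls)
      rep4 <- multiclass_report(mc)
      # benign-vs-malignant collapse: malignant (any subtype) = positive
      mal_t <- acc[[id]]$true != "Benign"
      mal_p <- acc[[id]]$pred != "Benign"
      ct <- confusion_table(TP = sum(mal_t & mal_p), TN = sum(!mal_t & !mal_p),
                            FP = sum(!mal_t & mal_p), FN = sum(mal_t & !mal_p))
      reports[[id]] <- list(
        task_id = id, split = split, kind = sp$kind,
        confusion = mc,
        metrics = suppressWarnings(binary_metrics(ct)),
        per_class = rep4$per_class,
        accuracy = rep4$overall_accuracy,
        kappa_paper = kappa_paper(ct),
        kappa_standard = kappa_standard(ct),
        dsc_mean = NA_real_, iou_mean = NA_real_,
        n_samples = length(samples))
    } else {
      ct <- confusion_table(acc[[id]]$TP, acc[[id]]$TN, acc[[id]]$FP,
                            acc[[id]]$FN)
      reports[[id]] <- list(
        task_id = id, split = split, kind = sp$kind,
        confusion = ct[c("TP", "TN", "FP", "FN")],
        metrics = suppressWarnings(binary_metrics(ct)),
        accuracy = ct$TP / ct$T_obs + ct$TN / ct$T_obs,
        kappa_paper = kappa_paper(ct),
        kappa_standard = kappa_standard(ct),
        dsc_mean = mean(acc[[id]]$dsc),
        iou_mean = mean(acc[[id]]$iou),
        n_samples = length(samples))
    }
  }
  reports
}

#' Two-stage (hierarchical) reading of 4-class probabilities
#'
#' First decides whether the cell is leukemic by comparing the benign
#' probability with the total malignant mass; if leukemic, assigns the
#' maturation subtype with the largest probability.  The flat argmax
#' over the four classes is the default everywhere else; this helper
#' provides the two-stage decision mode on the same softmax output.
#'
#' @param probs Length-4 probability vector or N x 4 matrix in
#'   [smear_classes()] order.
#' @param classes Class labels (benign class first).
#' @return Character vector of predicted labels.
#' @export
hierarchical_decision <- function(probs, classes = smear_classes()) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (ncol(probs) != length(classes))
    stop_invalid("probs must have one column per class")
  mal <- probs[, -1, drop = FALSE]
  sub <- classes[-1][max.col(mal, ties.method = "first")]
  ifelse(probs[, 1] >= rowSums(mal), classes[1], sub)
}

report_to_json <- function(reports, path) {
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

report_to_csv <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    m <- r$metrics
    data.frame(task_id = r$task_id, split = r$split, kind = r$kind,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               specificity = m$specificity, npv = m$npv,
               accuracy = r$accuracy,
               kappa_paper = r$kappa_paper,
               kappa_standard = r$kappa_standard,
               dsc_mean = r$dsc_mean, iou_mean = r$iou_mean,
               n_samples = r$n_samples)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
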
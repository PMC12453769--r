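# Training losses: binary cross-entropy, K-class cross-entropy, and the
# class-weighted binary focal loss used for nucleus segmentation.

#' Binary cross-entropy
#'
#' D = -[B ln F + (1 - B) ln(1 - F)], with the predicted probability
#' clamped to [eps, 1 - eps] before taking logs.
#'
#' @param B Ground truth in {0, 1} (vector-valued allowed).
#' @param F_pred Predicted probability in [0, 1].
#' @param eps Probability clamp (default 1e-7).
#' @return Mean loss over the supplied elements.
#' @export
bce_loss <- function(B, F_pred, eps = 1e-7) {
  if (any(F_pred < 0 | F_pred > 1))
    stop_invalid("predicted probabilities must lie in [0, 1]")
  p <- pmin(pmax(F_pred, eps), 1 - eps)
  mean(-(B * log(p) + (1 - B) * log(1 - p)))
}

#' Categorical cross-entropy
#'
#' -ln(probability assigned to the target class), for a K-class
#' distribution that sums to 1.
#'
#' @param target_class Integer class index (1-based) or vector of indices.
#' @param probs Length-K probability vector, or N x K matrix (one row per
#'   element of `target_class`).
#' @param eps Probability clamp.
#' @return Mean loss.
#' @export
categorical_ce <- function(target_class, probs, eps = 1e-7) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop_invalid("class probabilities must sum to 1")
  p <- probs[cbind(seq_along(target_class), target_class)]
  mean(-log(pmin(pmax(p, eps), 1 - eps)))
}

#' Background/foreground class-weighting factor
#'
#' a_c = N_b / N_f: the ratio of background to foreground pixels in a
#' binary mask, used to re-balance the focal loss.
#'
#' @param mask Binary mask (values in {0, 1}).
#' @return The scalar weight a_c.
#' @export
class_weight_factor <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop_invalid("mask must be binary")
  nf <- sum(mask == 1)
  if (nf == 0)
    stop("undefined class weight: mask has no foreground pixels",
         call. = FALSE)
  sum(mask == 0) / nf
}

#' Class-weighted binary focal loss
#'
#' Per-pixel loss
#' \deqn{l = -[a_c y (1-p_c)^\gamma \ln p_c + (1-y)^\gamma \ln(1-p_c)]}
#' averaged over pixels.  The positive term is down-weighted for easy
#' (high-probability) foreground pixels by the focusing factor
#' (1-p_c)^gamma and re-balanced by a_c = N_b/N_f.  As printed the
#' negative-class term carries no a_c weight and no p_c^gamma modulator;
#' `standard = TRUE` switches to the conventional symmetric form
#' -[a_c y (1-p)^g ln p + (1-y) p^g ln(1-p)].
#'
#' With gamma = 0 and a_c = 1 the loss reduces exactly to binary
#' cross-entropy.
#'
#' @param y Ground truth in {0, 1}.
#' @param p_c Predicted foreground probability.
#' @param a_c Class weight (default 1).
#' @param gamma Focusing parameter, >= 0 (default 2).
#' @param eps Probability clamp.
#' @param standard Use the conventional symmetric focal form.
#' @return Mean loss over pixels.
#' @export
focal_loss <- function(y, p_c, a_c = 1, gamma = 2, eps = 1e-7,
                       standard = FALSE) {
  if (gamma < 0) stop_invalid("gamma must be >= 0")
  p <- pmin(pmax(p_c, eps), 1 - eps)
  # for binary y the (1-y)^gamma factor gates the negative term: 1 when
  # y = 0, 0 when y = 1 (0^0 taken as 0 so gamma = 0 recovers BCE exactly)
  lpos <- -a_c * (1 - p)^gamma * log(p)
  lneg <- if (standard) -p^gamma * log(1 - p) else -log(1 - p)
  mean(y * lpos + (1 - y) * lneg)
}

# d(focal)/dp per element, same conventions as focal_loss
focal_loss_grad_p <- function(y, p_c, a_c = 1, gamma = 2, eps = 1e-7,
                              standard = FALSE) {
  p <- pmin(pmax(p_c, eps), 1 - eps)
  gpos <- a_c * (gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p)
  gneg <- if (standard) {
    -gamma * p^(gamma - 1) * log(1 - p) + p^gamma / (1 - p)
  } else {
    1 / (1 - p)
  }
  y * gpos + (1 - y) * gneg
}

#' Sum of per-task costs
#'
#' Total multi-task objective: sum of the task losses D_p over non-frozen
#' tasks.
#'
#' @param per_task_losses Named or unnamed numeric vector/list of task
#'   losses.
#' @param frozen Logical vector marking frozen tasks (contribute 0).
#' @return Scalar total loss.
#' @export
total_loss <- function(per_task_losses, frozen = NULL) {
  l <- unlist(per_task_losses)
  if (length(l) == 0) stop_invalid("at least one task loss required")
  if (!is.null(frozen)) l <- l[!frozen]
  sum(l)
}
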
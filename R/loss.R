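#' Balanced binary cross-entropy loss
#'
#' Mean per-pixel negative log-likelihood of the ground-truth mask under the
#' sigmoid of the predicted logits, computed in a numerically stable
#' softplus form:
#' `loss = mean( w * gt * softplus(-z) + (1 - gt) * softplus(z) )`,
#' where `w` is an optional foreground weight. `pos_weight = "balanced"`
#' sets `w` to the background/foreground pixel ratio of the batch.
#'
#' @param pred_logits Array of pre-sigmoid scores.
#' @param gt Binary ground-truth array of the same shape (values in {0, 1}).
#' @param pos_weight NULL (unweighted), a positive number, or `"balanced"`.
#' @return Non-negative scalar loss.
#' @export
balanced_bce_loss <- function(pred_logits, gt, pos_weight = NULL) {
  check_loss_inputs(pred_logits, gt)
  w <- resolve_pos_weight(pos_weight, gt)
  z <- as.numeric(pred_logits)
  g <- as.numeric(gt)
  sp_pos <- log1p(exp(-abs(z))) + pmax(-z, 0)
  sp_neg <- log1p(exp(-abs(z))) + pmax(z, 0)
  sum(w * g * sp_pos + (1 - g) * sp_neg) / length(z)
}

#' @rdname balanced_bce_loss
#' @return `balanced_bce_grad`: the analytic gradient of the loss with
#'   respect to the logits, same shape as `pred_logits`.
#' @export
balanced_bce_grad <- function(pred_logits, gt, pos_weight = NULL) {
  check_loss_inputs(pred_logits, gt)
  w <- resolve_pos_weight(pos_weight, gt)
  z <- pred_logits
  g <- gt
  s <- 1 / (1 + exp(-z))
  (-w * g * (1 - s) + (1 - g) * s) / length(z)
}

check_loss_inputs <- function(pred_logits, gt) {
  if (length(pred_logits) != length(gt))
    stop("balanced_bce_loss: shape mismatch between predictions and ground truth")
  if (!all(gt %in% c(0, 1)))
    stop("balanced_bce_loss: ground truth must be binary (0/1)")
  invisible(NULL)
}

resolve_pos_weight <- function(pos_weight, gt) {
  if (is.null(pos_weight)) return(1)
  if (identical(pos_weight, "balanced")) {
    nf <- sum(gt)
    if (nf == 0 || nf == length(gt)) return(1)
    return((length(gt) - nf) / nf)
  }
  if (!is.numeric(pos_weight) || pos_weight <= 0)
    stop("pos_weight must be NULL, a positive number, or \"balanced\"")
  pos_weight
}

#' Dice coefficient between two binary masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param pred_mask,gt_mask Binary arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coef <- function(pred_mask, gt_mask) {
  a <- as.numeric(pred_mask) > 0.5
  b <- as.numeric(gt_mask) > 0.5
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
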
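#' Pixel-level precision and recall
#'
#' Set-cardinality ratios over foreground pixels: precision is
#' `|SF ∩ GF| / |SF|` and recall `|SF ∩ GF| / |GF|`, where SF is the
#' predicted foreground set and GF the ground-truth foreground set. When a
#' set is empty: an empty prediction has precision 1 if the ground truth is
#' also empty, else 0; an empty ground truth has recall 1 if the prediction
#' is also empty, else NA.
#'
#' @param pred_mask,gt_mask Binary arrays of identical shape.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(pred_mask, gt_mask) {
  if (length(pred_mask) != length(gt_mask))
    stop("precision_recall: shape mismatch")
  sf <- as.numeric(pred_mask) > 0.5
  gf <- as.numeric(gt_mask) > 0.5
  inter <- sum(sf & gf)
  prec <- if (sum(sf) == 0) {
    if (sum(gf) == 0) 1 else 0
  } else inter / sum(sf)
  rec <- if (sum(gf) == 0) {
    if (sum(sf) == 0) 1 else NA_real_
  } else inter / sum(gf)
  c(precision = prec, recall = rec)
}

#' Average precision over score thresholds
#'
#' Sweeps the precision-recall curve over all distinct prediction scores
#' (pixels ranked by decreasing score), applies the monotone
#' non-increasing precision envelope, and integrates over recall.
#'
#' @param pred_probs Probability/score array.
#' @param gt_mask Binary array of the same shape with at least one
#'   foreground pixel.
#' @return List with `ap` and `pr_points` (a data frame of
#'   recall/precision pairs in sweep order).
#' @export
average_precision <- function(pred_probs, gt_mask) {
  if (length(pred_probs) != length(gt_mask))
    stop("average_precision: shape mismatch")
  g <- as.numeric(gt_mask) > 0.5
  npos <- sum(g)
  if (npos == 0) stop("average_precision: ground truth has no foreground (AP undefined)")
  s <- as.numeric(pred_probs)
  o <- order(s, decreasing = TRUE)
  gs <- g[o]
  ss <- s[o]
  tp <- cumsum(gs)
  fp <- cumsum(!gs)
  # one PR point per distinct score (threshold at that score, inclusive)
  last <- which(diff(ss) != 0)
  cut <- c(last, length(ss))
  prec <- tp[cut] / (tp[cut] + fp[cut])
  rec <- tp[cut] / npos
  # monotone precision envelope, then integrate over recall increments
  env <- rev(cummax(rev(prec)))
  dr <- diff(c(0, rec))
  ap <- sum(dr * env)
  list(ap = ap, pr_points = data.frame(recall = rec, precision = prec))
}

#' Mean average precision
#'
#' Arithmetic mean of per-class average precisions.
#'
#' @param ap_per_class Numeric vector of per-class APs (length >= 1).
#' @return Scalar mAP.
#' @export
mean_average_precision <- function(ap_per_class) {
  if (length(ap_per_class) == 0) stop("mean_average_precision: empty AP list")
  mean(as.numeric(ap_per_class))
}

#' Threshold a probability map
#'
#' @param prob_map Numeric array.
#' @param threshold Decision threshold in (0, 1).
#' @return Binary array (integer 0/1) of the same shape.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("binarize: threshold must lie in (0, 1)")
  out <- (prob_map >= threshold) + 0L
  dim(out) <- dim(prob_map)
  out
}

#' Evaluate a model on a dataset
#'
#' Computes pooled pixel-level precision and recall at the given threshold,
#' a per-class average precision (pixels of all samples of one class pooled
#' into one PR sweep), and their mean (mAP).
#'
#' @param model A `catu_model` or `catu_fit`.
#' @param dataset A `catu_dataset` or list of samples.
#' @param threshold Binarization threshold for precision/recall.
#' @return A `catu_metric_report` with `precision`, `recall`,
#'   `ap_per_class`, `map` and `pr_points`.
#' @export
evaluate_model <- function(model, dataset, threshold = 0.5) {
  if (inherits(model, "catu_fit")) model <- model$model
  samples <- as_sample_list(dataset)
  if (length(samples) == 0L) stop("evaluate_model: empty dataset")
  probs <- predict(model, samples)$prob
  gts <- lapply(samples, function(s) s$mask)
  classes <- vapply(samples, function(s) s$class_id %||% 1L, numeric(1))

  all_p <- unlist(probs)
  all_g <- unlist(gts)
  pr <- precision_recall(all_p >= threshold, all_g)

  ap_cls <- c()
  cls_levels <- sort(unique(classes))
  for (cl in cls_levels) {
    sel <- which(classes == cl)
    pc <- unlist(probs[sel])
    gc <- unlist(gts[sel])
    if (sum(gc) == 0) next
    ap_cls[as.character(cl)] <- average_precision(pc, gc)$ap
  }
  overall <- average_precision(all_p, all_g)
  rep <- list(precision = unname(pr["precision"]), recall = unname(pr["recall"]),
              ap_per_class = ap_cls, map = mean_average_precision(ap_cls),
              pr_points = overall$pr_points, threshold = threshold,
              n_samples = length(samples))
  class(rep) <- "catu_metric_report"
  rep
}

#' @export
print.catu_metric_report <- function(x, ...) {
  cat(sprintf("Pixel-level evaluation (%d samples, threshold %.2f)\n",
              x$n_samples, x$threshold))
  cat(sprintf("  precision: %.4f   recall: %.4f   mAP: %.4f\n",
              x$precision, x$recall, x$map))
  cat("  AP per class:",
      paste(sprintf("%s=%.3f", names(x$ap_per_class), x$ap_per_class), collapse = "  "),
      "\n")
  invisible(x)
}

#' Export a metric report
#'
#' Writes the report as JSON and, optionally, the PR curve as CSV.
#'
#' @param report A `catu_metric_report`.
#' @param path JSON output path.
#' @param pr_csv Optional CSV path for the PR points.
#' @export
write_metric_report <- function(report, path, pr_csv = NULL) {
  jsonlite::write_json(list(precision = report$precision, recall = report$recall,
                            ap_per_class = as.list(report$ap_per_class),
                            map = report$map, threshold = report$threshold,
                            n_samples = report$n_samples),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(pr_csv)) utils::write.csv(report$pr_points, pr_csv, row.names = FALSE)
  invisible(path)
}
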
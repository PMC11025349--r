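#' Pixelwise confusion counts between predicted and reference masks
#'
#' @param pred,gt binary matrices of equal shape.
#' @return list(TP, TN, FP, FN), non-negative pixel counts.
#' @export
confusion <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("confusion: mask shapes differ")
  stopifnot(is_binary(pred), is_binary(gt))
  tp <- sum(pred == 1 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Segmentation metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FP+FN), SPE = TN/(TN+FP), Recall = TP/(TP+FN),
#' IoU = TP/(TP+FP+FN). Any 0/0 is defined as 1 (empty-target convention)
#' and flagged in the `degenerate` field.
#'
#' @param counts list with TP, TN, FP, FN.
#' @return list(dice, spe, recall, iou, degenerate).
#' @export
seg_metrics <- function(counts) {
  safe <- function(num, den) if (den == 0) 1 else num / den
  with(counts, {
    degenerate <- (2 * TP + FP + FN == 0) || (TN + FP == 0) ||
      (TP + FN == 0)
    list(dice = safe(2 * TP, 2 * TP + FP + FN),
         spe = safe(TN, TN + FP),
         recall = safe(TP, TP + FN),
         iou = safe(TP, TP + FP + FN),
         degenerate = degenerate)
  })
}

#' Percentile bootstrap confidence interval for a per-image metric
#'
#' @param values per-image metric values (>= 2).
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return c(low, high).
#' @export
bootstrap_ci <- function(values, level = 0.95, n_boot = 2000, seed = 1L) {
  n <- length(values)
  if (n < 2) stop("bootstrap_ci: need at least 2 values")
  with_seed(seed, {
    means <- vapply(seq_len(n_boot), function(i)
      mean(values[sample.int(n, n, replace = TRUE)]), numeric(1))
    unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                    type = 7))
  })
}

#' Evaluate predicted masks against ground truth across a test set
#'
#' Per-image metrics are computed from each image's own confusion counts and
#' averaged (not pooled); the 95% CI on Dice is a percentile bootstrap over
#' images.
#'
#' @param preds,gts lists of binary masks, pairwise equal shapes.
#' @param n_boot bootstrap resamples for the Dice CI.
#' @param seed seed for the bootstrap.
#' @return list with `per_image` data frame, aggregate means (`dice`,
#'   `spe`, `recall`, `iou`), `n_images`, `ci_low`/`ci_high` for dice, and
#'   `aggregation = "averaged"`.
#' @export
evaluate_segmentation <- function(preds, gts, n_boot = 2000, seed = 1L) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1)
  rows <- lapply(seq_along(preds), function(i) {
    m <- seg_metrics(confusion(preds[[i]], gts[[i]]))
    data.frame(image = i, dice = m$dice, spe = m$spe, recall = m$recall,
               iou = m$iou, degenerate = m$degenerate)
  })
  per_image <- do.call(rbind, rows)
  ci <- if (nrow(per_image) >= 2)
    bootstrap_ci(per_image$dice, 0.95, n_boot, seed) else
    c(NA_real_, NA_real_)
  list(per_image = per_image,
       dice = mean(per_image$dice), spe = mean(per_image$spe),
       recall = mean(per_image$recall), iou = mean(per_image$iou),
       n_images = nrow(per_image), ci_low = ci[1], ci_high = ci[2],
       aggregation = "averaged")
}
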
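#' Pixel-wise segmentation metrics
#'
#' Confusion-matrix metrics between a predicted and a ground-truth binary
#' mask: accuracy (TP+TN)/N, precision TP/(TP+FP), recall TP/(TP+FN), and
#' F1 = 2PR/(P+R); ratios with zero denominator return 0. The loss is the
#' mean binary cross-entropy of the probability map against the truth (of
#' the clamped binary prediction when no probability map is supplied).
#'
#' @param pred predicted binary mask
#' @param truth ground-truth binary mask, same shape
#' @param prob optional probability map used for the loss
#' @return object of class `seg_metrics`: list with `accuracy`, `loss`,
#'   `precision`, `recall`, `f1` and the raw confusion counts
#' @export
evaluate_segmentation <- function(pred, truth, prob = NULL) {
  pred <- as_binary_mask(pred); truth <- as_binary_mask(truth)
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  seg_metrics_from_counts(tp, fp, fn, tn,
                          loss = bce_loss(if (is.null(prob)) pred else prob,
                                          truth))
}

seg_metrics_from_counts <- function(tp, fp, fn, tn, loss, epoch = NA_real_) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(accuracy = (tp + tn) / (tp + fp + fn + tn), loss = loss,
                 precision = precision, recall = recall, f1 = f1,
                 epoch = epoch,
                 counts = c(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f  loss %.4f  precision %.4f  recall %.4f  F1 %.4f%s\n",
    x$accuracy, x$loss, x$precision, x$recall, x$f1,
    if (is.na(x$epoch)) "" else sprintf("  epoch %.1f", x$epoch)))
  invisible(x)
}

#' Intersection over union of two binary masks
#'
#' @param a,b binary masks of equal shape
#' @return |a & b| / |a | b| (1 when both masks are empty)
#' @export
mask_iou <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  u <- sum(a == 1 | b == 1)
  if (u == 0) return(1)
  sum(a == 1 & b == 1) / u
}

#' Cross-validation configuration
#'
#' @param K number of folds (>= 2, default 10)
#' @param seed RNG seed for the fold partition
#' @param pretrain_dataset optional list of pairs used to pre-train each
#'   fold's model before fine-tuning (transfer learning)
#' @return object of class `crossval_config`
#' @export
crossval_config <- function(K = 10, seed = 1L, pretrain_dataset = NULL) {
  if (K < 2) stop("K must be >= 2")
  structure(list(K = as.integer(K), seed = as.integer(seed),
                 pretrain_dataset = pretrain_dataset),
            class = "crossval_config")
}

#' K-fold cross-validation of the U-Net
#'
#' Partitions the dataset by image (never by pixel) into K folds; each fold
#' in turn is held out, a fresh model is trained on the remaining K-1 folds
#' (after optional pre-training on `pretrain_dataset`) with the held-out
#' fold as the early-stopping validation set, and metrics are computed from
#' confusion counts pooled over all pixels of the held-out images. Fold
#' means are reported, including the mean stopping epoch.
#'
#' @param dataset list of `list(x=, y=)` pairs, length >= K
#' @param cv a [crossval_config()]
#' @param unet_cfg a [unet_config()]
#' @return list with `fold_metrics` (data.frame, one row per fold), `mean`
#'   (a `seg_metrics` of the fold means) and `folds` (the partition)
#' @export
cross_validate_unet <- function(dataset, cv = crossval_config(),
                                unet_cfg = unet_config()) {
  n <- length(dataset)
  if (cv$K > n) stop("K exceeds dataset size")
  set.seed(cv$seed)
  folds <- sample(rep_len(seq_len(cv$K), n))
  rows <- vector("list", cv$K)
  for (k in seq_len(cv$K)) {
    tr <- dataset[folds != k]
    va <- dataset[folds == k]
    cfg_k <- unet_cfg
    cfg_k$seed <- unet_cfg$seed + k
    model <- build_unet(cfg_k)
    if (!is.null(cv$pretrain_dataset)) {
      model <- train_unet(model, cv$pretrain_dataset, va, cfg_k)$model
    }
    fit <- train_unet(model, tr, va, cfg_k)
    tp <- fp <- fn <- tn <- 0; loss <- 0
    for (pr in va) {
      out <- predict_mask(fit$model, pr$x, prob = TRUE)
      loss <- loss + bce_loss(out$prob, pr$y)
      tp <- tp + sum(out$mask == 1 & pr$y == 1)
      fp <- fp + sum(out$mask == 1 & pr$y == 0)
      fn <- fn + sum(out$mask == 0 & pr$y == 1)
      tn <- tn + sum(out$mask == 0 & pr$y == 0)
    }
    m <- seg_metrics_from_counts(tp, fp, fn, tn, loss / length(va),
                                 epoch = fit$stop_epoch)
    rows[[k]] <- data.frame(fold = k, accuracy = m$accuracy, loss = m$loss,
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1, epoch = fit$stop_epoch)
  }
  fm <- do.call(rbind, rows)
  mean_metrics <- structure(list(accuracy = mean(fm$accuracy),
                                 loss = mean(fm$loss),
                                 precision = mean(fm$precision),
                                 recall = mean(fm$recall), f1 = mean(fm$f1),
                                 epoch = mean(fm$epoch), counts = NULL),
                            class = "seg_metrics")
  list(fold_metrics = fm, mean = mean_metrics, folds = folds)
}
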
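# Evaluation metrics for one-step predictions: global regression errors,
# threshold-free ranking AUCs, and F1 at a per-gene quantile operating point
# frozen on the training targets.

#' Global regression metrics
#'
#' RMSE, MAE and Pearson's r computed over the flattened prediction/target
#' arrays.
#'
#' @param pred,target numeric matrices (or vectors) of identical shape.
#' @return A list with `rmse`, `mae`, `pearson_r` (`NA` when the target has
#'   zero variance).
#' @export
evaluate_regression <- function(pred, target) {
  if (length(pred) == 0L || !identical(dim(pred), dim(target)))
    stop_lazynet("pred and target must be non-empty with identical shape",
                 class = "lazynet_validation_error")
  e <- as.numeric(pred) - as.numeric(target)
  r <- if (sd(as.numeric(target)) == 0) NA_real_
       else cor(as.numeric(pred), as.numeric(target))
  list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)), pearson_r = r)
}

#' Area under the ROC curve
#'
#' Tie-aware Mann-Whitney form: the probability that a random positive
#' outranks a random negative, counting ties as 1/2. Equivalent to
#' exhaustive pair counting.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) labels.
#' @return Scalar AUC in `[0, 1]`, `NA` if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision with tied scores grouped: summing
#' `(recall_k - recall_{k-1}) * precision_k` over distinct score levels in
#' decreasing order.
#'
#' @inheritParams roc_auc
#' @return Scalar PR-AUC in `[0, 1]`, `NA` if no positives.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || all(labels == 1L)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  n_pred <- grp_end
  prec <- tp / n_pred
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Threshold-free ranking metrics
#'
#' ROC-AUC and PR-AUC over the flattened continuous predictions against a
#' binarization of the targets. The positive class is defined by
#' `label_rule`, by default detection (`target > 0` on the modelling scale),
#' the natural binary event for sparse single-cell targets.
#'
#' @param pred,target numeric matrices of identical shape.
#' @param label_rule function mapping the target array to logical labels.
#' @return A list with `roc_auc` and `pr_auc` (`NA` when labels are
#'   single-class).
#' @export
evaluate_ranking <- function(pred, target, label_rule = function(y) y > 0) {
  if (!identical(dim(pred), dim(target)))
    stop_lazynet("pred and target must have identical shape",
                 class = "lazynet_shape_error")
  labels <- as.logical(label_rule(as.numeric(target)))
  s <- as.numeric(pred)
  list(roc_auc = roc_auc(s, labels), pr_auc = pr_auc(s, labels))
}

#' F1 at a per-gene quantile operating point
#'
#' A single per-gene threshold is learned once from the training targets via
#' a fixed quantile rule and frozen; predictions and evaluation targets are
#' then binarized at that threshold and micro-/macro-averaged F1 reported.
#' By default the quantile is matched to each gene's training positive rate
#' (threshold at the `1 - positive_rate` quantile); passing a numeric
#' `quantile` uses that fixed quantile for every gene. Genes absent from the
#' training matrix fall back to the global threshold. A gene with an empty
#' confusion numerator (`2 TP + FP + FN = 0`) contributes F1 = 0.
#'
#' @param train_targets genes x samples training target matrix (rownames are
#'   gene ids).
#' @param pred,target genes x samples evaluation matrices with rownames.
#' @param quantile numeric quantile in `[0, 1]`, or `NULL` for the
#'   positive-rate-matched rule.
#' @param label_rule rule defining the positive event on the target scale
#'   (used by the positive-rate-matched default).
#' @return A list with `f1_micro`, `f1_macro`, and the per-gene `thresholds`.
#' @export
f1_at_quantile_threshold <- function(train_targets, pred, target,
                                     quantile = NULL,
                                     label_rule = function(y) y > 0) {
  if (!identical(dim(pred), dim(target)))
    stop_lazynet("pred and target must have identical shape",
                 class = "lazynet_shape_error")
  genes <- rownames(pred) %||% sprintf("g%d", seq_len(nrow(pred)))
  tr_genes <- rownames(train_targets) %||%
    sprintf("g%d", seq_len(nrow(train_targets)))
  thr_for <- function(v) {
    q <- if (is.null(quantile)) 1 - mean(label_rule(v)) else quantile
    stats::quantile(v, min(max(q, 0), 1), names = FALSE, type = 7)
  }
  global_thr <- thr_for(as.numeric(train_targets))
  thresholds <- vapply(genes, function(g) {
    i <- match(g, tr_genes)
    if (is.na(i)) global_thr else thr_for(as.numeric(train_targets[i, ]))
  }, numeric(1))
  TP <- FP <- FN <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    ph <- pred[i, ] > thresholds[i]
    yh <- target[i, ] > thresholds[i]
    TP[i] <- sum(ph & yh); FP[i] <- sum(ph & !yh); FN[i] <- sum(!ph & yh)
  }
  f1 <- ifelse(2 * TP + FP + FN == 0, 0, 2 * TP / (2 * TP + FP + FN))
  denom <- 2 * sum(TP) + sum(FP) + sum(FN)
  list(f1_micro = if (denom == 0) 0 else 2 * sum(TP) / denom,
       f1_macro = mean(f1),
       thresholds = thresholds)
}
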
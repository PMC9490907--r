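#' Area under the ROC curve by rank concordance
#'
#' Mann-Whitney concordance of scores: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counting one half.
#' Invariant under any strictly monotone transform of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0))  # 1
#' auc_score(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 0.75
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required to compute AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Balanced accuracy at a fixed decision threshold
#'
#' Mean of sensitivity and specificity, i.e. prediction accuracy weighted by
#' the label proportions in the evaluation set.
#'
#' @param scores Numeric scores (probabilities).
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold on the score.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tpr <- mean(pred[labels == 1L] == 1L)
  tnr <- mean(pred[labels == 0L] == 0L)
  (tpr + tnr) / 2
}

#' Empirical ROC points
#'
#' Stepwise (FPR, TPR) pairs over descending score thresholds, including the
#' (0, 0) and (1, 1) endpoints.
#'
#' @param scores,labels As in [auc_score()].
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # step after each distinct threshold
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[keep]; fp <- cumsum(1 - y)[keep]
  data.frame(fpr = c(0, fp / sum(labels == 0L)),
             tpr = c(0, tp / sum(labels == 1L)))
}

#' Evaluate a trained model on a test set of bags
#'
#' @param model Trained `mil_model`.
#' @param bags List of `feature_bag`s (or matrices).
#' @param labels Binary labels (0/1).
#' @return List with `auc`, `balanced_accuracy`, `roc` (data frame) and
#'   `probs`.
#' @export
evaluate_fold <- function(model, bags, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("test set contains a single class; fold flagged", call. = FALSE)
  probs <- vapply(bags, predict_slide, numeric(1), model = model)
  list(auc = auc_score(probs, labels),
       balanced_accuracy = balanced_accuracy(probs, labels),
       roc = roc_points(probs, labels),
       probs = probs)
}

#' One-sample Wilcoxon signed-rank test (normal approximation)
#'
#' Tests whether values are symmetrically distributed around `mu`, using the
#' normal approximation with continuity correction. Zero differences are
#' dropped; ties in absolute differences receive average ranks.
#'
#' @param x Numeric values.
#' @param mu Null centre.
#' @return List with the signed-rank statistic `W` (sum of positive ranks),
#'   `z` and the two-sided `p.value`.
#' @examples
#' wilcoxon_signed_rank(seq(0.51, 0.60, by = 0.01), mu = 0.5)  # W = 55
#' @export
wilcoxon_signed_rank <- function(x, mu = 0.5) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) return(list(W = NA_real_, z = NA_real_, p.value = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mean_w <- n * (n + 1) / 4
  sd_w <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  cc <- sign(W - mean_w) * 0.5
  z <- (W - mean_w - cc) / sd_w
  list(W = W, z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Aggregate per-fold evaluation results
#'
#' Computes the mean AUC across Monte Carlo folds, compares the per-fold AUCs
#' to chance (0.5) with a one-sample Wilcoxon signed-rank test (normal
#' approximation with continuity correction), averages the ROC curves by
#' vertical averaging with linear interpolation on a fixed FPR grid, and
#' selects the best fold by the arithmetic mean of AUC and balanced accuracy.
#'
#' @param fold_results List of [evaluate_fold()] results.
#' @param fpr_grid FPR grid for vertical averaging.
#' @return List with `mean_auc`, `mean_balanced_accuracy`, `auc_wilcoxon`
#'   (test vs 0.5), `bacc_wilcoxon`, `avg_roc` (data frame `fpr`, `tpr`,
#'   `tpr_sd`), `best_fold`, and the per-fold `auc` / `balanced_accuracy`
#'   vectors.
#' @export
aggregate_folds <- function(fold_results, fpr_grid = seq(0, 1, by = 0.01)) {
  if (length(fold_results) < 2L) stop("need at least 2 folds", call. = FALSE)
  aucs <- vapply(fold_results, `[[`, numeric(1), "auc")
  baccs <- vapply(fold_results, `[[`, numeric(1), "balanced_accuracy")
  tprs <- vapply(fold_results, function(fr) {
    stats::approx(fr$roc$fpr, fr$roc$tpr, xout = fpr_grid,
                  ties = max, rule = 2)$y
  }, numeric(length(fpr_grid)))
  list(
    mean_auc = mean(aucs),
    mean_balanced_accuracy = mean(baccs),
    auc_wilcoxon = wilcoxon_signed_rank(aucs, 0.5),
    bacc_wilcoxon = wilcoxon_signed_rank(baccs, 0.5),
    avg_roc = data.frame(fpr = fpr_grid, tpr = rowMeans(tprs),
                         tpr_sd = apply(tprs, 1, stats::sd)),
    best_fold = which.max((aucs + baccs) / 2),
    auc = aucs, balanced_accuracy = baccs
  )
}
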
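## Screening and classification performance metrics shared by the
## fingerprint-classification, docking-rescoring and orchestration stages.

#' ROC AUC by the rank statistic
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counting one half (Mann-Whitney formulation).
#'
#' @param scores numeric scores, higher = more active.
#' @param labels 0/1 labels (both classes present).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present for ROC AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Empirical ROC curve as (FPR, TPR) points including (0,0) and (1,1),
## one point per distinct threshold (upper staircase).
rocCurve <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(1L - lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each tie block
  tpr <- c(0, tp[keep] / sum(lab))
  fpr <- c(0, fp[keep] / sum(1L - lab))
  list(fpr = fpr, tpr = tpr)
}

#' Semilogarithmic ROC AUC (logAUC)
#'
#' Area under the ROC curve with the false-positive rate on a log10 axis,
#' emphasising early enrichment. The FPR axis is clipped to [1e-3, 1], the
#' TPR is linearly interpolated at the lower bound, the area is computed by
#' the trapezoid rule over log10(FPR), and the result is normalised by the
#' 3 decades so a perfect ranker scores 1 and the chance diagonal scores
#' (1 - 1e-3)/(3 ln 10) = 0.1446.
#'
#' @param scores,labels as in \code{\link{rocAuc}}.
#' @param fpr,tpr alternatively, an explicit ROC curve (monotone point set).
#' @param min_fpr lower clipping bound of the FPR axis (default 1e-3).
#' @return logAUC in [0, 1].
#' @export
logAuc <- function(scores = NULL, labels = NULL, fpr = NULL, tpr = NULL,
                   min_fpr = 1e-3) {
  if (is.null(fpr)) {
    cur <- rocCurve(scores, labels)
    fpr <- cur$fpr; tpr <- cur$tpr
  }
  # upper staircase: best achievable TPR at each distinct FPR
  tpr_u <- tapply(tpr, fpr, max)
  fpr_u <- as.numeric(names(tpr_u))
  tpr_u <- as.numeric(tpr_u)
  if (max(fpr_u) < 1) { fpr_u <- c(fpr_u, 1); tpr_u <- c(tpr_u, 1) }
  t_at_min <- approx(fpr_u, tpr_u, xout = min_fpr, rule = 2, ties = max)$y
  keep <- fpr_u > min_fpr
  x <- c(log10(min_fpr), log10(fpr_u[keep]))
  yv <- c(t_at_min, tpr_u[keep])
  area <- sum(diff(x) * (head(yv, -1) + yv[-1]) / 2)
  area / (-log10(min_fpr))
}

#' Enrichment factor in the top fraction of a ranked list
#'
#' Fraction of actives among the top ceiling(alpha * N) ranked compounds,
#' divided by the overall active fraction.
#'
#' @param scores numeric scores, higher ranks first.
#' @param labels 0/1 labels.
#' @param alpha top fraction (e.g. 0.01 for EF at 1\%); \code{alpha * N}
#'   must be at least 1.
#' @return non-negative enrichment factor.
#' @export
efAtFraction <- function(scores, labels, alpha) {
  labels <- as.integer(labels)
  N <- length(scores)
  if (alpha * N < 1) stop("alpha * N < 1: top slice would be empty")
  top_n <- ceiling(alpha * N)
  ord <- order(scores, decreasing = TRUE)
  hits <- sum(labels[ord][seq_len(top_n)])
  (hits / top_n) / (sum(labels) / N)
}

#' Binary classification metric suite
#'
#' Accuracy, balanced accuracy (mean of sensitivity and specificity),
#' sensitivity, specificity, F1 (harmonic mean of precision and recall),
#' ROC AUC (from \code{y_score} when given) and the Matthews correlation
#' coefficient MCC = (TP TN - FP FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A zero MCC denominator yields 0; with a single class in \code{y_true}
#' the AUC and MCC are returned as \code{NA} with a warning.
#'
#' @param y_true,y_pred 0/1 vectors.
#' @param y_score optional numeric scores for the AUC.
#' @return named numeric vector of metrics.
#' @export
classificationMetrics <- function(y_true, y_pred, y_score = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  TP <- sum(y_true == 1L & y_pred == 1L)
  TN <- sum(y_true == 0L & y_pred == 0L)
  FP <- sum(y_true == 0L & y_pred == 1L)
  FN <- sum(y_true == 1L & y_pred == 0L)
  single_class <- length(unique(y_true)) < 2L
  acc <- (TP + TN) / length(y_true)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spc <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  bacc <- mean(c(sens, spc))
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  rec <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (single_class) NA_real_ else if (denom == 0) 0 else
    (TP * TN - FP * FN) / denom
  auc <- if (single_class || is.null(y_score)) NA_real_ else rocAuc(y_score, y_true)
  if (single_class) warning("single-class y_true: AUC and MCC undefined")
  c(accuracy = acc, bACC = bacc, sensitivity = sens, specificity = spc,
    F1 = f1, roc_auc = auc, MCC = mcc)
}

#' Binary Tanimoto (Jaccard) similarity
#'
#' Number of features shared by two binary fingerprints divided by the
#' number of features present in either. Two all-zero fingerprints are
#' defined as identical (similarity 1) with a warning.
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in [0, 1].
#' @export
binaryTanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.numeric(a != 0); b <- as.numeric(b != 0)
  union <- sum(a + b > 0)
  if (union == 0) {
    warning("both fingerprints empty; similarity defined as 1")
    return(1)
  }
  sum(a * b) / union
}

#' Generalized (count-vector) Tanimoto similarity
#'
#' sum(min(a_i, b_i)) / sum(max(a_i, b_i)) over a shared vocabulary; both
#' vectors all-zero yields 1 with a warning. Named vectors must share the
#' vocabulary.
#'
#' @param a,b non-negative count vectors.
#' @return similarity in [0, 1].
#' @export
countSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("count vectors differ in vocabulary length")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    stop("count vectors have mismatched vocabularies")
  }
  denom <- sum(pmax(a, b))
  if (denom == 0) {
    warning("both count vectors empty; similarity defined as 1")
    return(1)
  }
  sum(pmin(a, b)) / denom
}
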
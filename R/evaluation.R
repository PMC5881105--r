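# Threshold-dependent metrics (sensitivity, specificity, accuracy, MCC),
# ROC/AUC, the pairwise AUC comparison test, and model evaluation.

#' Confusion counts for binary calls
#'
#' @param labels Binary reference labels (0/1).
#' @param calls Binary predicted calls (0/1), same length.
#' @return List with `tp`, `fn`, `tn`, `fp`, `ps` (= TP + FN, positives)
#'   and `ns` (= TN + FP, negatives).
#' @export
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 1, 0))
confusionCounts <- function(labels, calls) {
  labels <- as.integer(labels); calls <- as.integer(calls)
  if (length(labels) != length(calls)) stop("labels and calls differ in length")
  if (length(labels) == 0L) stop("empty input")
  if (!all(labels %in% 0:1) || !all(calls %in% 0:1))
    stop("labels and calls must be 0/1")
  tp <- sum(labels == 1L & calls == 1L)
  fn <- sum(labels == 1L & calls == 0L)
  tn <- sum(labels == 0L & calls == 0L)
  fp <- sum(labels == 0L & calls == 1L)
  list(tp = tp, fn = fn, tn = tn, fp = fp, ps = tp + fn, ns = tn + fp)
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity `TP/PS`, specificity `TN/NS`, accuracy `(TP+TN)/(PS+NS)`
#' and the Matthews correlation coefficient by the standard
#' product-moment formula
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any marginal is zero.
#'
#' @param counts Output of [confusionCounts()].
#' @return List with `sensitivity`, `specificity`, `accuracy`, `mcc`.
#' @export
thresholdMetrics <- function(counts) {
  if (counts$ps < 1L || counts$ns < 1L)
    stop("both classes must be present (PS >= 1 and NS >= 1)")
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  list(sensitivity = tp / counts$ps,
       specificity = tn / counts$ns,
       accuracy = (tp + tn) / (counts$ps + counts$ns),
       mcc = mcc)
}

#' Intuitive-form MCC (cross-check)
#'
#' The algebraically equivalent "intuitive" MCC form popular in the
#' peptide-prediction literature,
#' `(1 - (FN/PS + FP/NS)) / sqrt((1 + (FP-FN)/PS) (1 + (FN-FP)/NS))`,
#' kept as an independent cross-check of [thresholdMetrics()]'s standard
#' formula (the two agree to floating-point precision whenever all four
#' marginals are positive).
#'
#' @inheritParams thresholdMetrics
#' @return The MCC value.
#' @export
mccChou <- function(counts) {
  ps <- counts$ps; ns <- counts$ns
  if (ps < 1L || ns < 1L) stop("both classes must be present")
  num <- 1 - (counts$fn / ps + counts$fp / ns)
  den <- (1 + (counts$fp - counts$fn) / ps) *
         (1 + (counts$fn - counts$fp) / ns)
  if (den <= 0) return(0)
  num / sqrt(den)
}

#' ROC curve and AUC
#'
#' AUC is computed by the rank (Mann-Whitney) formulation with ties
#' contributing 1/2, which equals the trapezoidal area under the step ROC
#' curve. The curve steps through the distinct score values in descending
#' order (call positive when score `>=` threshold) and is anchored at
#' (0, 0) and (1, 1).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1); both classes must be present.
#' @return List with `auc` and `curve` (data frame: `threshold`, `fpr`,
#'   `tpr`).
#' @export
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), c(1, 1, 0, 1, 0, 0))$auc  # 8/9
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores must match labels")
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nNeg,
                numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1)
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  list(auc = auc, curve = curve)
}

#' Welch t-test comparing two per-repeat AUC samples
#'
#' Two-tailed Welch (unequal-variance) two-sample t-test on per-repeat AUC
#' values from repeated cross-validation, as used to compare classifier
#' families.
#'
#' @param aucsA,aucsB Numeric vectors of per-repeat AUCs (length >= 2).
#' @return List with `statistic`, `df`, `p.value`.
#' @export
compareAUC <- function(aucsA, aucsB) {
  if (length(aucsA) < 2L || length(aucsB) < 2L)
    stop("need at least 2 AUC values per sample")
  if (sd(aucsA) == 0 && sd(aucsB) == 0)
    stop("both samples have zero variance; add repeats or jitter ",
         "before comparing")
  ht <- t.test(aucsA, aucsB, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Evaluate a model bundle on a labeled dataset
#'
#' Computes the full metric report at the bundle's probability cutoff plus
#' the AUC from the raw probabilities. If the encoded evaluation matrix
#' fingerprints identically to the bundle's training matrix a leakage
#' warning is emitted (the report is still produced).
#'
#' @param bundle A [ModelBundle-class].
#' @param dataset A labeled [PeptideSet-class].
#' @return One-row data frame: `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`, `accuracy`, `mcc`, `auc`, `cutoff`.
#' @export
evaluateModel <- function(bundle, dataset) {
  stopifnot(is(bundle, "ModelBundle"), is(dataset, "PeptideSet"))
  labels <- peptideLabels(dataset)
  if (anyNA(labels)) stop("dataset must be fully labeled for evaluation")
  preds <- predict(bundle, dataset)
  m <- encodeDataset(dataset, bundle@encoder$name,
                     parts = if (is.null(bundle@encoder$parts)) HYBRID_ORDER
                             else bundle@encoder$parts,
                     denominator = bundle@encoder$dpcDenominator %||% "length")
  if (identical(matrixFingerprint(subsetMatrix(m, bundle@features)),
                bundle@fingerprint))
    warning("evaluation data fingerprint matches the training matrix; ",
            "metrics are optimistic (training-set evaluation)")
  counts <- confusionCounts(labels, preds$class)
  tm <- thresholdMetrics(counts)
  data.frame(tp = counts$tp, fn = counts$fn, tn = counts$tn, fp = counts$fp,
             sensitivity = tm$sensitivity, specificity = tm$specificity,
             accuracy = tm$accuracy, mcc = tm$mcc,
             auc = rocAuc(preds$probability, labels)$auc,
             cutoff = bundle@cutoff)
}
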
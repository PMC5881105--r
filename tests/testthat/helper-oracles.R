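# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths so that dual-route checks stay meaningful.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomPeptide <- function(len) {
  paste(sample(AAS, len, replace = TRUE), collapse = "")
}

randomPeptideSet <- function(n, lenRange = c(5, 25), labels = NULL) {
  seqs <- vapply(seq_len(n),
                 function(i) randomPeptide(sample(lenRange[1]:lenRange[2], 1)),
                 character(1))
  PeptideSet(seqs, ids = paste0("r", seq_len(n)), labels = labels)
}

# Longest-common-subsequence identity by dynamic programming; the same
# quantity the implementation obtains from a unit-score global alignment.
lcsIdentity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1L, j + 1L] <- if (x[i] == y[j]) d[i, j] + 1L else
      max(d[i, j + 1L], d[i + 1L, j])
  }
  d[n + 1L, m + 1L] / min(n, m)
}

# Standard product-moment MCC, written out directly.
mccOracle <- function(tp, fn, tn, fp) {
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
}

# Brute-force pair-counting AUC (ties count 1/2).
pairAUC <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (q in sn) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# Trapezoidal area under the empirical step ROC curve.
trapezoidAUC <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nNeg,
                numeric(1))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# A small fast profile catalogue wrapper for modeling tests.
tinyGrid <- list(ntree = 150L, mtry = 10L, nsplit = 2L)
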
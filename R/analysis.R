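# Compositional and positional enrichment statistics comparing a positive
# and a negative peptide set (two-sample-logo-style, statistics only).

.welchP <- function(a, b) {
  # Welch t on per-peptide values. With zero variance in both groups the
  # statistic is 0/0: undefined (NA) at equal means, a sure difference
  # (p = 0) otherwise.
  if (sd(a) == 0 && sd(b) == 0)
    return(if (mean(a) == mean(b)) NA_real_ else 0)
  tryCatch(t.test(a, b, var.equal = FALSE)$p.value,
           error = function(e) NA_real_)
}

#' Compositional enrichment between two peptide classes
#'
#' Per residue (`level = "aac"`) or ordered dipeptide (`level = "dpc"`),
#' compares the per-peptide composition values of the positive and
#' negative sets with a two-sided Welch t-test. The t-test units are the
#' per-peptide frequencies, not pooled counts. Items where neither class
#' shows any variance are flagged `no_variance` with `p = NA`.
#'
#' @param pos,neg [PeptideSet-class] objects (>= 2 peptides each).
#' @param level `"aac"` or `"dpc"`.
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05, uncorrected).
#' @param adjust Multiple-testing adjustment passed to
#'   [stats::p.adjust()]; default `"none"` (raw p-values), with
#'   `"BH"` available.
#' @return Data frame sorted by ascending p: `item`, `mean_pos`,
#'   `mean_neg`, `diff`, `p`, `significant`, `no_variance`; the fraction
#'   of significant items (among testable ones) is attached as attribute
#'   `significant_fraction`.
#' @export
compositionEnrichment <- function(pos, neg, level = c("aac", "dpc"),
                                  alpha = 0.05, adjust = "none") {
  level <- match.arg(level)
  stopifnot(is(pos, "PeptideSet"), is(neg, "PeptideSet"))
  if (length(pos) < 2L || length(neg) < 2L)
    stop("each class needs at least 2 peptides (variance undefined otherwise)")
  mp <- encodeDataset(pos, level)
  mn <- encodeDataset(neg, level)
  items <- sub(paste0("^", toupper(level), "_"), "", colnames(mp))
  p <- vapply(seq_along(items), function(j) .welchP(mp[, j], mn[, j]),
              numeric(1))
  p <- p.adjust(p, method = adjust)
  out <- data.frame(item = items,
                    mean_pos = colMeans(mp), mean_neg = colMeans(mn),
                    diff = colMeans(mp) - colMeans(mn),
                    p = p, significant = !is.na(p) & p <= alpha,
                    no_variance = is.na(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$item), ]
  rownames(out) <- NULL
  attr(out, "significant_fraction") <-
    mean(out$significant[!out$no_variance])
  out
}

#' Positional residue enrichment between two peptide classes
#'
#' For each of the first `nPositions` positions from the chosen terminus
#' and each residue, compares per-peptide occupancy indicators (1 when the
#' residue sits at that position) between classes with a two-sample Welch
#' t-test. C-terminal positions are indexed 1..n from the last residue
#' inward. Peptides shorter than a position simply do not contribute to
#' it; positions beyond every peptide yield no rows.
#'
#' @inheritParams compositionEnrichment
#' @param terminus `"N"` or `"C"`.
#' @param nPositions Number of terminal positions to test (default 10).
#' @return Data frame: `position`, `residue`, `mean_pos`, `mean_neg`,
#'   `diff`, `p`, `significant`, `no_variance`.
#' @export
positionalEnrichment <- function(pos, neg, terminus = c("N", "C"),
                                 nPositions = 10L, alpha = 0.05) {
  terminus <- match.arg(terminus)
  stopifnot(is(pos, "PeptideSet"), is(neg, "PeptideSet"))
  if (length(pos) < 2L || length(neg) < 2L)
    stop("each class needs at least 2 peptides")
  residueAt <- function(seqs, j) {
    L <- nchar(seqs)
    at <- if (terminus == "N") j else L - j + 1L
    ok <- L >= j
    ifelse(ok, substr(seqs, at, at), NA_character_)
  }
  sp <- as.character(peptides(pos))
  sn <- as.character(peptides(neg))
  rows <- list()
  for (j in seq_len(nPositions)) {
    rp <- residueAt(sp, j); rn <- residueAt(sn, j)
    rp <- rp[!is.na(rp)]; rn <- rn[!is.na(rn)]
    if (length(rp) < 2L || length(rn) < 2L) next
    for (aa in AA_ALPHABET) {
      ip <- as.numeric(rp == aa); ineg <- as.numeric(rn == aa)
      if (sum(ip) == 0 && sum(ineg) == 0) next
      p <- .welchP(ip, ineg)
      rows[[length(rows) + 1L]] <- data.frame(
        position = j, residue = aa,
        mean_pos = mean(ip), mean_neg = mean(ineg),
        diff = mean(ip) - mean(ineg), p = p,
        significant = !is.na(p) & p <= alpha,
        no_variance = is.na(p), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(position = integer(0), residue = character(0),
                      mean_pos = numeric(0), mean_neg = numeric(0),
                      diff = numeric(0), p = numeric(0),
                      significant = logical(0), no_variance = logical(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$position, out$residue), ]
  rownames(out) <- NULL
  out
}
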
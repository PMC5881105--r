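# The five fixed-length peptide encodings and their hybrid concatenation.
# Feature vectors are named numeric vectors; dataset-level encoding stacks
# them into a peptides x features matrix. All encoders are deterministic.

.seqChars <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("a single sequence string is required")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  alien <- setdiff(chars, AA_ALPHABET)
  if (length(alien) > 0L)
    stop("non-canonical residue(s): ", paste(alien, collapse = ", "))
  if (length(chars) == 0L) stop("empty sequence")
  chars
}

#' Amino acid composition (AAC)
#'
#' The fraction of each of the 20 canonical residues in the peptide:
#' `AAC(i) = count(i) / length`. The 20 values sum to 1 and are ordered
#' alphabetically A..Y.
#'
#' @param sequence Peptide sequence string (canonical residues only).
#' @return Named numeric vector of length 20 (`AAC_A` .. `AAC_Y`).
#' @export
#' @examples
#' encodeAAC("KLKLLLLLKLK")[c("AAC_K", "AAC_L")]
encodeAAC <- function(sequence) {
  chars <- .seqChars(sequence)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts) / length(chars),
                  paste0("AAC_", AA_ALPHABET))
}

#' Dipeptide composition (DPC)
#'
#' Frequencies of the 400 ordered residue pairs among the `L - 1`
#' overlapping dipeptides of the sequence, in fixed lexicographic order
#' `AA, AC, ..., YY`. With the default denominator (`"length"`, i.e.
#' `L - 1`) the 400 values sum to 1; `denominator = "constant"` divides the
#' counts by 400 instead, a uniform rescaling kept as an option.
#'
#' @inheritParams encodeAAC
#' @param denominator `"length"` (default) or `"constant"`.
#' @return Named numeric vector of length 400 (`DPC_AA` .. `DPC_YY`).
#' @export
#' @examples
#' encodeDPC("ACAC")[c("DPC_AC", "DPC_CA")]
encodeDPC <- function(sequence, denominator = c("length", "constant")) {
  denominator <- match.arg(denominator)
  chars <- .seqChars(sequence)
  L <- length(chars)
  if (L < 2L) stop("dipeptide composition requires length >= 2")
  dips <- paste0(chars[-L], chars[-1L])
  counts <- table(factor(dips, levels = DIPEPTIDES))
  denom <- if (denominator == "length") L - 1L else 400L
  stats::setNames(as.numeric(counts) / denom, paste0("DPC_", DIPEPTIDES))
}

#' AAindex-weighted composition (AAI)
#'
#' Composition weighted by the mean of eight min-max-normalized
#' high-quality AAindex scales (see [aaiProfile()]):
#' `AAI(i) = AAC(i) * meanNormalizedIndex(i)`. A 20-value,
#' length-independent vector with entries in `[0, 1]`.
#'
#' @inheritParams encodeAAC
#' @return Named numeric vector of length 20 (`AAI_A` .. `AAI_Y`).
#' @export
encodeAAI <- function(sequence) {
  aac <- encodeAAC(sequence)
  stats::setNames(as.numeric(aac) * aaiProfile(), paste0("AAI_", AA_ALPHABET))
}

.ctdDistribution <- function(positions, L) {
  # positions: 1-based residue positions of one group's members
  m <- length(positions)
  if (m == 0L) return(rep(0, 5L))
  idx <- pmax(1L, ceiling(c(0.25, 0.5, 0.75, 1) * m))
  positions[c(1L, idx)] / L * 100
}

#' Composition-transition-distribution descriptors (CTD)
#'
#' For each of seven physicochemical attributes the 20 residues are split
#' into three groups (see `CTD_SCHEMES` in the package sources). Per
#' attribute the descriptor has 21 values: composition C (percent of
#' residues per group, summing to 100), transition T (percent of adjacent
#' residue pairs crossing each unordered group pair, out of `L - 1`), and
#' distribution D (for each group, the sequence positions -- as percent of
#' `L` -- of its first, 25%, 50%, 75% and 100% occurrence, using
#' `ceiling(fraction * groupCount)` with minimum 1; an absent group yields
#' five zeros). The seven attributes concatenate to 147 features.
#'
#' @inheritParams encodeAAC
#' @return Named numeric vector of length 147.
#' @export
#' @examples
#' v <- encodeCTD("KLKLLLLLKLK")
#' sum(v[grep("hydrophobicity_C", names(v))])  # 100
encodeCTD <- function(sequence) {
  chars <- .seqChars(sequence)
  L <- length(chars)
  if (L < 2L) stop("CTD requires length >= 2 (transitions need a pair)")
  out <- numeric(0)
  for (prop in names(CTD_SCHEMES)) {
    scheme <- CTD_SCHEMES[[prop]]
    grp <- integer(L)
    for (g in 1:3) grp[chars %in% scheme[[g]]] <- g
    comp <- as.numeric(table(factor(grp, levels = 1:3))) / L * 100
    pairs <- cbind(grp[-L], grp[-1L])
    tr <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(gp) {
      sum((pairs[, 1] == gp[1] & pairs[, 2] == gp[2]) |
          (pairs[, 1] == gp[2] & pairs[, 2] == gp[1]))
    }, numeric(1)) / (L - 1L) * 100
    dist <- unlist(lapply(1:3, function(g) .ctdDistribution(which(grp == g), L)))
    vals <- c(comp, tr, dist)
    names(vals) <- paste0("CTD_", prop, "_",
                          c(paste0("C_", 1:3),
                            c("T_12", "T_13", "T_23"),
                            paste0("D_", rep(1:3, each = 5L), "_",
                                   rep(c("first", "q25", "q50", "q75", "q100"), 3L))))
    out <- c(out, vals)
  }
  out
}

#' Physicochemical property descriptors (PCP)
#'
#' Nine scalar descriptors: fractions of hydrophobic (F,I,W,L,V,M,Y,C,A),
#' hydrophilic (R,K,N,D,E,P), neutral (T,H,G,S,Q), positively charged
#' (K,H,R) and negatively charged (D,E) residues; the turn-forming fraction
#' `(N+G+P+S)/n`; the absolute net charge per residue
#' `|count(K)+count(R) - count(D) - count(E)|/n`; the molecular weight per
#' residue (sum of average residue masses plus one water, divided by `n`);
#' and the aliphatic index `(A + 2.9 V + 3.9 I + 3.9 L)/n` with residue
#' counts.
#'
#' @inheritParams encodeAAC
#' @return Named numeric vector of length 9.
#' @export
#' @examples
#' encodePCP("VVLL")["PCP_aliphatic_index"]  # (2.9*2 + 3.9*2)/4 = 3.4
encodePCP <- function(sequence) {
  chars <- .seqChars(sequence)
  n <- length(chars)
  cnt <- function(set) sum(chars %in% set)
  k <- cnt("K"); r <- cnt("R"); d <- cnt("D"); e <- cnt("E")
  vals <- c(
    cnt(PCP_GROUPS$hydrophobic) / n,
    cnt(PCP_GROUPS$hydrophilic) / n,
    cnt(PCP_GROUPS$neutral) / n,
    cnt(PCP_GROUPS$positive) / n,
    cnt(PCP_GROUPS$negative) / n,
    cnt(PCP_GROUPS$turn) / n,
    abs(k + r - d - e) / n,
    (sum(RESIDUE_MASS[chars]) + WATER_MASS) / n,
    (cnt("A") + 2.9 * cnt("V") + 3.9 * cnt("I") + 3.9 * cnt("L")) / n)
  stats::setNames(vals, PCP_FEATURE_NAMES)
}

HYBRID_ORDER <- c("aac", "aai", "dpc", "ctd", "pcp")

#' Hybrid encoding: concatenation of selected encoders
#'
#' Concatenates the requested encoder blocks in the fixed order
#' AAC, AAI, DPC, CTD, PCP. The full hybrid has
#' `20 + 20 + 400 + 147 + 9 = 596` features.
#'
#' @inheritParams encodeDPC
#' @param parts Non-empty subset of `c("aac", "aai", "dpc", "ctd", "pcp")`.
#' @return Named numeric vector.
#' @export
#' @examples
#' length(encodeHybrid("KLKLLLLLKLK"))  # 596
encodeHybrid <- function(sequence, parts = HYBRID_ORDER,
                         denominator = c("length", "constant")) {
  parts <- tolower(parts)
  if (length(parts) == 0L) stop("`parts` must be non-empty")
  bad <- setdiff(parts, HYBRID_ORDER)
  if (length(bad) > 0L)
    stop("unknown encoder part(s): ", paste(bad, collapse = ", "))
  parts <- HYBRID_ORDER[HYBRID_ORDER %in% parts]
  blocks <- lapply(parts, function(p) {
    switch(p,
           aac = encodeAAC(sequence),
           aai = encodeAAI(sequence),
           dpc = encodeDPC(sequence, denominator),
           ctd = encodeCTD(sequence),
           pcp = encodePCP(sequence))
  })
  do.call(c, blocks)
}

#' Encode a whole dataset into a feature matrix
#'
#' Applies one encoder to every record of a [PeptideSet-class]; row `i` of
#' the result equals the single-sequence encoding of record `i`, with
#' peptide ids as row names and a fixed column order across calls.
#'
#' @param x A [PeptideSet-class].
#' @param encoder One of `"aac"`, `"aai"`, `"dpc"`, `"ctd"`, `"pcp"`,
#'   `"hybrid"`.
#' @param parts For `encoder = "hybrid"`: the blocks to concatenate.
#' @param denominator DPC denominator convention, see [encodeDPC()].
#' @return Numeric matrix, peptides x features.
#' @export
#' @examples
#' ps <- PeptideSet(c(p1 = "KLKLLLLLKLK", p2 = "ACDEFG"))
#' dim(encodeDataset(ps, "dpc"))  # 2 x 400
encodeDataset <- function(x, encoder = c("dpc", "aac", "aai", "ctd", "pcp",
                                         "hybrid"),
                          parts = HYBRID_ORDER,
                          denominator = c("length", "constant")) {
  stopifnot(is(x, "PeptideSet"))
  encoder <- match.arg(encoder)
  denominator <- match.arg(denominator)
  seqs <- as.character(peptides(x))
  ids <- peptideIds(x)
  rows <- lapply(seq_along(seqs), function(i) {
    tryCatch(
      switch(encoder,
             aac = encodeAAC(seqs[i]),
             aai = encodeAAI(seqs[i]),
             dpc = encodeDPC(seqs[i], denominator),
             ctd = encodeCTD(seqs[i]),
             pcp = encodePCP(seqs[i]),
             hybrid = encodeHybrid(seqs[i], parts, denominator)),
      error = function(e) stop("record '", ids[i], "': ",
                               conditionMessage(e), call. = FALSE))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  m
}

#' Write / read a feature matrix as TSV
#'
#' Tab-separated with a header row of feature names and a first column
#' (`id`) of peptide ids. Lines starting with `#` are ignored on read and
#' an optional provenance `header` comment can be written.
#'
#' @param m Feature matrix (peptides x features).
#' @param path File path.
#' @param header Optional comment line(s) written before the table.
#' @export
writeFeatureMatrix <- function(m, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  tab <- read.delim(path, header = TRUE, comment.char = "#",
                    check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  m
}
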
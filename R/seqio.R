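#' Construct a PeptideSet
#'
#' Validates and assembles peptide records. Lowercase residues are uppercased
#' with a warning; any residue outside the 20-letter canonical alphabet, a
#' sequence shorter than 2 residues, or a duplicated id is an error.
#'
#' @param sequences Character vector of peptide sequences.
#' @param ids Character vector of unique identifiers; defaults to
#'   `names(sequences)`.
#' @param labels Optional vector of binary labels (0/1/`NA`), recycled `NA`
#'   when absent.
#' @return A [PeptideSet-class] object.
#' @export
#' @examples
#' ps <- PeptideSet(c(p1 = "KLKLLLLLKLK", p2 = "ACDEFGH"), labels = c(1, 0))
#' nPositives(ps)
PeptideSet <- function(sequences, ids = names(sequences), labels = NULL) {
  force(ids)  # capture names before as.character() strips them
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("no sequences supplied")
  if (is.null(ids)) stop("peptide ids are required (names or `ids=`)")
  ids <- as.character(ids)
  if (any(grepl("[a-z]", sequences))) {
    warning("lowercase residues uppercased")
    sequences <- toupper(sequences)
  }
  ok <- validateSequences(sequences, ids)
  if (!isTRUE(ok)) stop(ok)
  if (is.null(labels)) {
    labels <- rep(NA_integer_, length(sequences))
  } else {
    if (length(labels) != length(sequences))
      stop("labels must be parallel to sequences")
    labels <- as.integer(labels)
  }
  seqs <- AAStringSet(sequences)
  names(seqs) <- ids
  new("PeptideSet", sequences = seqs, labels = labels)
}

#' @rdname PeptideSet-class
#' @export
setMethod("peptideIds", "PeptideSet", function(x) names(x@sequences))

#' @rdname PeptideSet-class
#' @export
setMethod("peptides", "PeptideSet", function(x) x@sequences)

#' @rdname PeptideSet-class
#' @export
setMethod("peptideLabels", "PeptideSet", function(x) {
  stats::setNames(x@labels, names(x@sequences))
})

#' @rdname PeptideSet-class
#' @export
setMethod("nPositives", "PeptideSet",
          function(x) sum(x@labels == 1L, na.rm = TRUE))

#' @rdname PeptideSet-class
#' @export
setMethod("nNegatives", "PeptideSet",
          function(x) sum(x@labels == 0L, na.rm = TRUE))

#' @rdname PeptideSet-class
#' @export
setMethod("length", "PeptideSet", function(x) length(x@sequences))

#' @rdname PeptideSet-class
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = TRUE) {
  new("PeptideSet", sequences = x@sequences[i], labels = x@labels[i])
})

setMethod("show", "PeptideSet", function(object) {
  n <- length(object)
  w <- width(object@sequences)
  cat("PeptideSet with", n, "record(s)\n")
  cat("  lengths:", min(w), "-", max(w), "residues\n")
  cat("  labeled:", sum(!is.na(object@labels)),
      sprintf("(%d positive, %d negative)\n",
              nPositives(object), nNegatives(object)))
})

#' Read peptides from a FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file, validates every
#' record against the canonical 20-letter alphabet and attaches binary class
#' labels. Labels can come from a two-column tab-separated table
#' (`id<TAB>label`, no header) or from a `>id|label` header convention
#' (detected when every header ends in `|0` or `|1`).
#'
#' @param path FASTA file path.
#' @param labels Optional path to a label TSV.
#' @return A [PeptideSet-class].
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "KLKLLLLLKLK", ">p2", "ACDEFG"), fa)
#' readFasta(fa)
readFasta <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(readAAStringSet(path, format = "fasta"),
                   error = function(e) stop("not a readable FASTA file: ",
                                            path, " (", conditionMessage(e), ")"))
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  headers <- sub("\\s.*$", "", names(seqs))
  lab <- rep(NA_integer_, length(seqs))
  if (is.null(labels) && all(grepl("\\|[01]$", headers))) {
    lab <- as.integer(sub("^.*\\|", "", headers))
    headers <- sub("\\|[01]$", "", headers)
  }
  ps <- PeptideSet(as.character(seqs), ids = headers, labels = lab)
  if (!is.null(labels)) ps <- attachLabels(ps, labels)
  ps
}

#' Attach labels from a two-column TSV (id, label; no header)
#'
#' @param x A [PeptideSet-class].
#' @param path Label table path.
#' @return `x` with labels joined by id; ids absent from the table keep `NA`.
#' @export
attachLabels <- function(x, path) {
  if (!file.exists(path)) stop("label table not found: ", path)
  tab <- read.delim(path, header = FALSE, colClasses = "character",
                    col.names = c("id", "label"))
  if (!all(tab$label %in% c("0", "1")))
    stop("labels must be 0 or 1; offending value(s): ",
         paste(unique(setdiff(tab$label, c("0", "1"))), collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate id(s) in label table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  unknown <- setdiff(tab$id, peptideIds(x))
  if (length(unknown) > 0L)
    warning("label table ids absent from dataset: ",
            paste(head(unknown, 5L), collapse = ", "))
  m <- match(peptideIds(x), tab$id)
  lab <- ifelse(is.na(m), NA_integer_, as.integer(tab$label[m]))
  x@labels <- lab
  validObject(x)
  x
}

#' Write a PeptideSet to FASTA (and optionally its labels to TSV)
#'
#' `readFasta(writeFasta(x, path))` round-trips ids and sequences exactly.
#' Writing an empty dataset is refused.
#'
#' @param x A [PeptideSet-class].
#' @param path Output FASTA path.
#' @export
writeFasta <- function(x, path) {
  stopifnot(is(x, "PeptideSet"))
  if (length(x) == 0L) stop("refusing to write an empty dataset")
  writeXStringSet(x@sequences, filepath = path, format = "fasta")
  invisible(path)
}

#' @rdname writeFasta
#' @details `writeLabels()` writes the labeled records as an `id<TAB>label`
#'   table (no header), the format accepted by [attachLabels()].
#' @export
writeLabels <- function(x, path) {
  stopifnot(is(x, "PeptideSet"))
  keep <- !is.na(x@labels)
  if (!any(keep)) stop("no labeled records to write")
  write.table(data.frame(id = peptideIds(x)[keep], label = x@labels[keep]),
              file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pairwise sequence identity under a unit-score global alignment
#'
#' Identity is the number of aligned matches under a global alignment with
#' match score 1 and zero mismatch/gap penalties, divided by the length of
#' the shorter sequence (the convention of common redundancy-reduction
#' tools).
#'
#' @param a,b Peptide sequence strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwiseIdentity("KLKLLLK", "KLKLLAK")
pairwiseIdentity <- function(a, b) {
  pa <- pairwiseAlignment(a, b, type = "global",
                          substitutionMatrix = identityMatrix(),
                          gapOpening = 0, gapExtension = 0)
  nmatch(pa) / min(nchar(a), nchar(b))
}

#' Greedy redundancy reduction by pairwise identity
#'
#' A simple deterministic Hobohm-style stand-in for word-filter clustering
#' tools: records are visited longest-first (ties by id, ascending) and a
#' record is kept iff its identity ([pairwiseIdentity()]) to every
#' previously kept record is below `identityThreshold`. Kept records are
#' returned in their original input order. This is NOT an exact
#' reproduction of CD-HIT.
#'
#' @param x A [PeptideSet-class].
#' @param identityThreshold Fraction in (0, 1]; records at or above this
#'   identity to a kept record are dropped.
#' @return A reduced [PeptideSet-class].
#' @export
#' @examples
#' ps <- PeptideSet(c(a = "KLKLLLLLKLK", b = "KLKLLLLLKLK", c = "ACDEFGH"))
#' length(reduceRedundancy(ps, 0.8))
reduceRedundancy <- function(x, identityThreshold = 0.8) {
  stopifnot(is(x, "PeptideSet"))
  if (!is.numeric(identityThreshold) || length(identityThreshold) != 1L ||
      identityThreshold <= 0 || identityThreshold > 1)
    stop("identityThreshold must be a single value in (0, 1]")
  seqs <- as.character(peptides(x))
  ids <- peptideIds(x)
  ord <- order(-nchar(seqs), ids)
  kept <- integer(0)
  for (i in ord) {
    redundant <- FALSE
    for (k in kept) {
      if (pairwiseIdentity(seqs[i], seqs[k]) >= identityThreshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  x[sort(kept)]
}
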
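#' PeptideSet: validated peptides with optional binary labels
#'
#' Holds an ordered collection of peptide records: unique identifiers,
#' sequences over the 20-letter canonical amino acid alphabet (minimum
#' length 2, so that dipeptide composition is defined) and an optional
#' binary class label per record (1 = positive/AIP, 0 = negative, `NA` =
#' unlabeled).
#'
#' @slot sequences An [Biostrings::AAStringSet] with unique names (the ids).
#' @slot labels Integer vector parallel to `sequences`; values 0, 1 or `NA`.
#'
#' @seealso [PeptideSet()], [readFasta()], [peptideIds()], [peptideLabels()]
#' @export
setClass("PeptideSet",
  representation(sequences = "AAStringSet", labels = "integer"))

setValidity("PeptideSet", function(object) {
  seqs <- as.character(object@sequences)
  ids <- names(object@sequences)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    return("every record needs a non-empty id")
  if (anyDuplicated(ids))
    return(paste0("duplicate id(s): ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@labels) != length(seqs))
    return("labels must be parallel to sequences")
  if (!all(object@labels %in% c(0L, 1L, NA_integer_)))
    return("labels must be 0, 1 or NA")
  bad <- validateSequences(seqs, ids)
  if (!isTRUE(bad)) return(bad)
  TRUE
})

# Returns TRUE or a message; shared by the class validity and readFasta.
validateSequences <- function(seqs, ids) {
  n <- nchar(seqs)
  if (any(n < 2L))
    return(paste0("sequence(s) shorter than 2 residues (dipeptide ",
                  "composition undefined): ",
                  paste(ids[n < 2L], collapse = ", ")))
  for (i in seq_along(seqs)) {
    letters_i <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    alien <- setdiff(letters_i, AA_ALPHABET)
    if (length(alien) > 0L)
      return(paste0("record '", ids[i], "' contains non-canonical residue(s): ",
                    paste(alien, collapse = ", ")))
  }
  TRUE
}

#' FISTable: per-feature importance scores
#'
#' Impurity-based feature importance scores (FIS) averaged over the trees of
#' cross-validation-grown random forests and renormalized to sum to one.
#'
#' @slot features Character vector of unique feature names, in the column
#'   order of the matrix the scores were estimated from.
#' @slot scores Non-negative numeric vector parallel to `features`, summing
#'   to 1.
#'
#' @seealso [estimateFIS()], [generateFeatureSets()]
#' @export
setClass("FISTable",
  representation(features = "character", scores = "numeric"))

setValidity("FISTable", function(object) {
  if (length(object@features) != length(object@scores))
    return("features and scores must have equal length")
  if (length(object@features) == 0L) return("empty FIS table")
  if (anyDuplicated(object@features)) return("feature names must be unique")
  if (any(!is.finite(object@scores)) || any(object@scores < 0))
    return("scores must be finite and non-negative")
  if (abs(sum(object@scores) - 1) > 1e-6)
    return("scores must sum to 1 (normalized importances)")
  TRUE
})

#' ModelBundle: a trained peptide classifier and everything needed to reuse it
#'
#' Couples a fitted model with its algorithm id, tuned hyperparameters,
#' selected feature names, probability cutoff, class order, the encoder
#' specification (including a version tag checked at prediction time) and a
#' fingerprint of the training matrix used for leakage warnings.
#'
#' @slot algorithm One of `"RF"`, `"ERT"`, `"SVM"`, `"KNN"`.
#' @slot params Named list of hyperparameters for the algorithm.
#' @slot features Character vector of selected feature names (model input
#'   order).
#' @slot cutoff Probability cutoff in (0, 1); calls are positive when the
#'   positive-class probability is `>=` the cutoff.
#' @slot classOrder Length-2 character, `c(negative, positive)`.
#' @slot model The fitted model object.
#' @slot encoder Named list: `name` (encoder id), `parts` (hybrid parts or
#'   `NULL`), `dpcDenominator`, `version`.
#' @slot fingerprint MD5 fingerprint of the training feature matrix.
#' @slot version Package version string at training time.
#'
#' @seealso [trainFinal()], [runPipeline()], [saveBundle()], [loadBundle()]
#' @export
setClass("ModelBundle",
  representation(algorithm = "character", params = "list",
                 features = "character", cutoff = "numeric",
                 classOrder = "character", model = "ANY",
                 encoder = "list", fingerprint = "character",
                 version = "character"))

setValidity("ModelBundle", function(object) {
  if (!object@algorithm %in% c("RF", "ERT", "SVM", "KNN"))
    return("algorithm must be one of RF, ERT, SVM, KNN")
  if (length(object@features) == 0L) return("feature set must be non-empty")
  if (length(object@cutoff) != 1L || object@cutoff <= 0 || object@cutoff >= 1)
    return("cutoff must be a single value in (0, 1)")
  if (length(object@classOrder) != 2L)
    return("classOrder must be c(negative, positive)")
  TRUE
})
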
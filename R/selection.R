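# Random-forest feature-importance estimation and the cutoff-thresholded
# candidate feature-set sweep.

#' FISTable constructor
#'
#' @param features Feature names.
#' @param scores Non-negative importances; renormalized to sum to 1.
#' @return A [FISTable-class].
#' @export
FISTable <- function(features, scores) {
  s <- sum(scores)
  if (s <= 0) stop("importance scores sum to zero")
  new("FISTable", features = as.character(features),
      scores = as.numeric(scores) / s)
}

#' @rdname FISTable-class
#' @export
setMethod("fisFeatures", "FISTable", function(x) x@features)

#' @rdname FISTable-class
#' @export
setMethod("fisScores", "FISTable",
          function(x) stats::setNames(x@scores, x@features))

#' @rdname FISTable-class
#' @export
setMethod("length", "FISTable", function(x) length(x@features))

setMethod("show", "FISTable", function(object) {
  cat("FISTable over", length(object@features), "features\n")
  o <- order(-object@scores)
  top <- head(o, 5L)
  cat("  top:", paste(sprintf("%s=%.4g", object@features[top],
                              object@scores[top]), collapse = ", "), "\n")
})

#' @rdname FISTable-class
#' @param row.names,optional,... Passed to [base::as.data.frame()] methods.
#' @export
setMethod("as.data.frame", "FISTable",
  function(x, row.names = NULL, optional = FALSE, ...) {
    o <- order(-x@scores, x@features)
    data.frame(feature = x@features[o], score = x@scores[o],
               stringsAsFactors = FALSE)
  })

#' Write / read a FIS table as two-column TSV (feature, score)
#'
#' Rows are ordered by descending score.
#' @param x A [FISTable-class] (for `writeFIS`).
#' @param path File path.
#' @export
writeFIS <- function(x, path) {
  stopifnot(is(x, "FISTable"))
  write.table(as.data.frame(x), file = path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeFIS
#' @export
readFIS <- function(path) {
  tab <- read.delim(path, header = TRUE, comment.char = "#")
  FISTable(tab$feature, tab$score)
}

# Deterministic small sub-seed derivation (kept well below 2^31).
mixSeed <- function(seed, a = 0L, b = 0L, c = 0L) {
  as.integer((as.numeric(seed) %% 1e6) + a * 7919 + b * 131 + c) %% 2147483629L
}

#' Estimate feature importance scores with cross-validated forests
#'
#' For each cross-validation round a forest is grown on the training fold
#' with the per-tree number of split candidates (`mtry`) drawn uniformly
#' from `[mtryLow, mtryHigh]`; this is realized by partitioning the
#' `nTrees` trees into equal sub-forests, one per `mtry` value, which is
#' equivalent in expectation. Impurity (Gini) importances are averaged over
#' all trees of a fold, normalized per fold, averaged unweighted across
#' folds (and optional repeats) and renormalized to sum to one.
#'
#' @param m Feature matrix (peptides x features).
#' @param labels Binary labels (0/1) parallel to rows.
#' @param folds Number of CV folds (default 5).
#' @param nTrees Total trees per round (default 10000).
#' @param mtryLow,mtryHigh Range of per-tree split-candidate counts
#'   (defaults 1 and 50; clamped to the number of features with a warning).
#' @param repeats Number of CV repetitions to average over (default 1).
#' @param seed Integer seed; the result is deterministic given it.
#' @return A [FISTable-class] in the column order of `m`.
#' @export
estimateFIS <- function(m, labels, folds = 5L, nTrees = 10000L,
                        mtryLow = 1L, mtryHigh = 50L, repeats = 1L,
                        seed = 1L) {
  labels <- as.integer(labels)
  if (nrow(m) != length(labels)) stop("matrix rows must match labels")
  if (anyNA(labels)) stop("all records must be labeled")
  if (length(unique(labels)) < 2L) stop("labels are constant; FIS undefined")
  if (folds < 2L) stop("folds must be >= 2")
  if (nrow(m) < folds) stop("fewer rows than folds")
  if (mtryHigh > ncol(m)) {
    warning("mtryHigh clamped to the number of features (", ncol(m), ")")
    mtryHigh <- ncol(m)
  }
  if (mtryLow > mtryHigh) stop("mtryLow must be <= mtryHigh")
  y <- factor(labels, levels = c(0L, 1L))
  mtries <- seq.int(mtryLow, mtryHigh)
  nm <- length(mtries)
  treesPer <- rep(nTrees %/% nm, nm)
  extra <- nTrees %% nm
  if (extra > 0L) treesPer[seq_len(extra)] <- treesPer[seq_len(extra)] + 1L
  acc <- numeric(ncol(m))
  nRounds <- 0L
  for (r in seq_len(repeats)) {
    plan <- cvPlan(folds = folds, repeats = 1L, seed = mixSeed(seed, 1L, r))
    foldId <- makeFolds(nrow(m), labels, plan)[[1L]]
    for (f in seq_len(folds)) {
      train <- foldId != f
      impSum <- numeric(ncol(m))
      total <- 0L
      for (j in seq_len(nm)) {
        if (treesPer[j] == 0L) next
        fit <- ranger(x = m[train, , drop = FALSE], y = y[train],
                      num.trees = treesPer[j], mtry = mtries[j],
                      importance = "impurity", probability = FALSE,
                      seed = mixSeed(seed, r, f, j), num.threads = 1L)
        impSum <- impSum + importance(fit) * treesPer[j]
        total <- total + treesPer[j]
      }
      perTree <- impSum / total
      s <- sum(perTree)
      acc <- acc + if (s > 0) perTree / s else rep(1 / ncol(m), ncol(m))
      nRounds <- nRounds + 1L
    }
  }
  FISTable(colnames(m), acc / nRounds)
}

#' Generate nested candidate feature sets from a FIS cutoff sweep
#'
#' Features with FIS below `floor` are dropped first; then one feature set
#' is produced per cutoff value in `{cutoffLow, cutoffLow + step, ...,
#' cutoffHigh}` (inclusive; the grid is built by integer stepping so
#' floating-point accumulation cannot change the set count). Each set keeps
#' the features with FIS `>=` its cutoff, ordered by descending FIS (ties
#' by name), so the sets are nested by construction. With the defaults the
#' sweep has exactly 35 cutoffs. A cutoff retaining zero features is
#' skipped with a warning.
#'
#' @param fis A [FISTable-class].
#' @param cutoffLow,cutoffHigh,step Sweep bounds and step (defaults 0.0005,
#'   0.0039, 0.0001).
#' @param floor Minimum FIS a feature needs to enter the sweep at all
#'   (default 0.0005).
#' @return List of feature sets; each is a list with elements `cutoff` and
#'   `features`.
#' @export
generateFeatureSets <- function(fis, cutoffLow = 0.0005, cutoffHigh = 0.0039,
                                step = 0.0001, floor = 0.0005) {
  stopifnot(is(fis, "FISTable"))
  if (step <= 0) stop("step must be positive")
  if (cutoffLow > cutoffHigh) stop("cutoffLow must be <= cutoffHigh")
  scores <- fisScores(fis)
  scores <- scores[scores >= floor]
  if (length(scores) == 0L) stop("no features survive the FIS floor")
  o <- order(-scores, names(scores))
  scores <- scores[o]
  nSteps <- round((cutoffHigh - cutoffLow) / step)
  cutoffs <- cutoffLow + step * (0:nSteps)
  sets <- list()
  for (ct in cutoffs) {
    keep <- names(scores)[scores >= ct]
    if (length(keep) == 0L) {
      warning(sprintf("cutoff %.6g retains no features; skipped", ct))
      next
    }
    sets[[length(sets) + 1L]] <- list(cutoff = ct, features = keep)
  }
  sets
}

#' Column-subset a feature matrix to a feature set
#'
#' @param m Feature matrix.
#' @param fset A feature set from [generateFeatureSets()] (or any list with
#'   a `features` element), or a character vector of feature names.
#' @return The matrix restricted to the set's columns, in set order.
#' @export
subsetMatrix <- function(m, fset) {
  feats <- if (is.character(fset)) fset else fset$features
  if (length(feats) == 0L) stop("empty feature set")
  missing <- setdiff(feats, colnames(m))
  if (length(missing) > 0L)
    stop("feature(s) absent from matrix: ", paste(missing, collapse = ", "))
  m[, feats, drop = FALSE]
}
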
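# Repeated stratified cross-validation, grid search over four classifier
# families, consensus (median) hyperparameters, final training, probability
# cutoff tuning and the end-to-end pipeline.

#' Cross-validation plan
#'
#' @param folds Number of folds (>= 2).
#' @param repeats Number of repetitions (>= 1); repeat `r` derives its fold
#'   partition from `seed + r - 1`.
#' @param seed Integer seed.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @return A list of class `cvPlan`.
#' @export
cvPlan <- function(folds = 5L, repeats = 10L, seed = 1L, stratified = TRUE) {
  folds <- as.integer(folds); repeats <- as.integer(repeats)
  if (folds < 2L) stop("folds must be >= 2")
  if (repeats < 1L) stop("repeats must be >= 1")
  structure(list(folds = folds, repeats = repeats, seed = as.integer(seed),
                 stratified = stratified), class = "cvPlan")
}

#' Stratified fold assignments
#'
#' Per repeat, every record is assigned to exactly one test fold; with
#' stratification, per-fold class counts are within one record of the
#' global class proportions. Deterministic given the plan's seed.
#'
#' @param n Number of records.
#' @param labels Binary labels (0/1), length `n`.
#' @param plan A [cvPlan()].
#' @return List with one integer fold-assignment vector (values
#'   `1..folds`) per repeat.
#' @export
makeFolds <- function(n, labels, plan) {
  stopifnot(inherits(plan, "cvPlan"))
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must have length n")
  if (anyNA(labels)) stop("all records must be labeled")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < plan$folds))
    stop("a class has fewer members (", min(counts),
         ") than folds (", plan$folds, ")")
  lapply(seq_len(plan$repeats), function(r) {
    set.seed(mixSeed(plan$seed, 0L, r))
    foldId <- integer(n)
    groups <- if (plan$stratified) split(seq_len(n), labels) else
      list(seq_len(n))
    for (idx in groups) {
      shuffled <- sample(idx)
      foldId[shuffled] <- rep_len(seq_len(plan$folds), length(idx))
    }
    foldId
  })
}

#' Hyperparameter container
#'
#' Only fields relevant to the algorithm are used: `ntree`, `mtry`,
#' `nsplit` (minimum samples to split a node) for forests (RF/ERT);
#' `cost`, `gamma` for the RBF SVM; `k` for k-NN.
#'
#' @param algorithm One of `"RF"`, `"ERT"`, `"SVM"`, `"KNN"`.
#' @param ... Named numeric parameter values.
#' @return A list of class `hyperParams`.
#' @export
#' @examples
#' hyperParams("RF", ntree = 430, mtry = 1, nsplit = 2)
hyperParams <- function(algorithm = c("RF", "ERT", "SVM", "KNN"), ...) {
  algorithm <- match.arg(algorithm)
  vals <- list(...)
  allowed <- switch(algorithm,
                    RF = c("ntree", "mtry", "nsplit"),
                    ERT = c("ntree", "mtry", "nsplit"),
                    SVM = c("cost", "gamma", "probability"),
                    KNN = "k")
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0L)
    stop("parameter(s) not used by ", algorithm, ": ",
         paste(bad, collapse = ", "))
  structure(c(list(algorithm = algorithm), vals), class = "hyperParams")
}

#' Default hyperparameter grids
#'
#' Forests: `ntree` 50 to 990 by 20 with 1000 appended (the printed range
#' "50 to 1,000 step 20" does not land on 1000, so it is added explicitly),
#' `mtry` 1..7, `nsplit` 2..10. SVM: `cost` `2^seq(-5, 15, 2)`, `gamma`
#' `2^seq(-15, 3, 2)`. KNN: odd `k` 1..31.
#'
#' @param algorithm One of `"RF"`, `"ERT"`, `"SVM"`, `"KNN"`.
#' @return Named list of parameter value vectors.
#' @export
defaultGrid <- function(algorithm = c("RF", "ERT", "SVM", "KNN")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         RF = ,
         ERT = list(ntree = c(seq(50L, 990L, by = 20L), 1000L),
                    mtry = 1:7, nsplit = 2:10),
         SVM = list(cost = 2^seq(-5, 15, by = 2),
                    gamma = 2^seq(-15, 3, by = 2)),
         KNN = list(k = seq(1L, 31L, by = 2L)))
}

# -- internal learners --------------------------------------------------------

# Class order convention everywhere: c("0", "1") = (negative, positive).
.fitModel <- function(algorithm, x, y, params, seed) {
  switch(algorithm,
    RF = ranger(x = x, y = y, num.trees = params$ntree, mtry = params$mtry,
                min.node.size = params$nsplit, probability = TRUE,
                seed = seed, num.threads = 1L),
    ERT = ranger(x = x, y = y, num.trees = params$ntree, mtry = params$mtry,
                 min.node.size = params$nsplit, probability = TRUE,
                 splitrule = "extratrees", replace = FALSE,
                 sample.fraction = 1, seed = seed, num.threads = 1L),
    SVM = svm(x = x, y = y, cost = params$cost, gamma = params$gamma,
              kernel = "radial",
              probability = !isFALSE(params$probability)),
    KNN = list(train = x, cl = y, k = params$k, seed = seed),
    stop("unknown algorithm: ", algorithm))
}

.predictProb <- function(algorithm, model, x) {
  switch(algorithm,
    RF = ,
    ERT = predict(model, data = x, num.threads = 1L)$predictions[, "1"],
    SVM = {
      if (isFALSE(model$compprob))
        stop("SVM was fitted without probability calibration; ",
             "retrain with probability = TRUE")
      p <- predict(model, x, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    },
    KNN = {
      set.seed(model$seed)  # knn breaks ties at random
      pred <- knn(train = model$train, test = x, cl = model$cl, k = model$k,
                  prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    stop("unknown algorithm: ", algorithm))
}

# Out-of-fold positive-class probabilities for one fold partition.
.oofProbs <- function(m, y, foldId, algorithm, params, seed) {
  probs <- numeric(nrow(m))
  for (f in sort(unique(foldId))) {
    test <- foldId == f
    if (length(unique(y[!test])) < 2L)
      stop("degenerate fold: training data contain a single class")
    fit <- .fitModel(algorithm, m[!test, , drop = FALSE], y[!test], params,
                     mixSeed(seed, f))
    probs[test] <- .predictProb(algorithm, fit, m[test, , drop = FALSE])
  }
  probs
}

# Mean per-fold out-of-fold AUC for one fold partition.
.cvAUC <- function(m, y, foldId, algorithm, params, seed) {
  aucs <- vapply(sort(unique(foldId)), function(f) {
    test <- foldId == f
    if (length(unique(y[!test])) < 2L)
      stop("degenerate fold: training data contain a single class")
    fit <- .fitModel(algorithm, m[!test, , drop = FALSE], y[!test], params,
                     mixSeed(seed, f))
    p <- .predictProb(algorithm, fit, m[test, , drop = FALSE])
    rocAuc(p, as.integer(as.character(y[test])))$auc
  }, numeric(1))
  mean(aucs)
}

.gridCombos <- function(grid) {
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  combos[do.call(order, combos), , drop = FALSE]
}

#' Grid search with repeated cross-validation
#'
#' For every repeat of the plan, evaluates every parameter combination by
#' mean out-of-fold AUC and returns the per-repeat best combination with
#' its metrics. Ties are broken toward smaller parameter values in grid
#' order (for forests: smaller `ntree`, then `mtry`, then `nsplit`).
#'
#' @param m Feature matrix.
#' @param labels Binary labels (0/1).
#' @param algorithm One of `"RF"`, `"ERT"`, `"SVM"`, `"KNN"`.
#' @param grid Named list of parameter vectors (see [defaultGrid()]).
#' @param plan A [cvPlan()].
#' @return List with `best` (list of per-repeat [hyperParams()]) and
#'   `metrics` (data frame: repeat, parameters, mean out-of-fold `auc`).
#' @export
gridSearch <- function(m, labels, algorithm = c("RF", "ERT", "SVM", "KNN"),
                       grid = defaultGrid(algorithm), plan = cvPlan()) {
  algorithm <- match.arg(algorithm)
  if (length(grid) == 0L || any(lengths(grid) == 0L))
    stop("grid must be non-empty")
  labels <- as.integer(labels)
  if (nrow(m) != length(labels)) stop("matrix rows must match labels")
  y <- factor(labels, levels = c(0L, 1L))
  foldsPerRepeat <- makeFolds(nrow(m), labels, plan)
  combos <- .gridCombos(grid)
  best <- vector("list", plan$repeats)
  rows <- list()
  for (r in seq_len(plan$repeats)) {
    aucs <- vapply(seq_len(nrow(combos)), function(ci) {
      params <- as.list(combos[ci, , drop = FALSE])
      .cvAUC(m, y, foldsPerRepeat[[r]], algorithm, params,
             mixSeed(plan$seed, r, ci))
    }, numeric(1))
    bi <- which.max(aucs)  # combos pre-sorted ascending: first max wins ties
    best[[r]] <- do.call(hyperParams,
                         c(list(algorithm = algorithm),
                           as.list(combos[bi, , drop = FALSE])))
    rows[[r]] <- cbind(data.frame(repeat_ = r), combos[bi, , drop = FALSE],
                       data.frame(auc = aucs[bi]))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(best = best, metrics = metrics)
}

#' Consensus (median) hyperparameters across repeats
#'
#' Element-wise median of each numeric parameter across the per-repeat best
#' parameter sets, optionally snapped to the nearest grid point (ties
#' toward the smaller value).
#'
#' @param perRepeat List of [hyperParams()] with a common algorithm.
#' @param grid Optional named list of grid vectors to snap to.
#' @return A [hyperParams()].
#' @export
#' @examples
#' hp <- lapply(c(410, 450), function(nt)
#'   hyperParams("RF", ntree = nt, mtry = 1, nsplit = 2))
#' consensusParams(hp, defaultGrid("RF"))$ntree  # 430
consensusParams <- function(perRepeat, grid = NULL) {
  if (length(perRepeat) == 0L) stop("at least one repeat is required")
  algos <- unique(vapply(perRepeat, `[[`, character(1), "algorithm"))
  if (length(algos) != 1L)
    stop("mixed algorithms: ", paste(algos, collapse = ", "))
  fields <- setdiff(names(perRepeat[[1L]]), "algorithm")
  vals <- lapply(fields, function(f) {
    med <- median(vapply(perRepeat, function(p) as.numeric(p[[f]]),
                         numeric(1)))
    if (!is.null(grid[[f]])) {
      g <- sort(as.numeric(grid[[f]]))
      d <- abs(g - med)
      med <- g[which.min(d)]  # ties resolved toward the smaller grid value
    }
    med
  })
  names(vals) <- fields
  do.call(hyperParams, c(list(algorithm = algos), vals))
}

# Deterministic fingerprint of a feature matrix (values + dimnames).
matrixFingerprint <- function(m) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(colnames(m), rownames(m),
               format(as.numeric(m), digits = 15)), tmp)
  unname(md5sum(tmp))
}

#' Train the final model on the full matrix
#'
#' Fits the given algorithm on `m` restricted to the feature set, with the
#' probability cutoff initialized to 0.5 (tune it afterwards with
#' [tuneCutoff()]). The returned bundle embeds the selected feature names,
#' the encoder specification and a fingerprint of the training matrix;
#' bundles round-trip through [saveBundle()]/[loadBundle()] with identical
#' predictions.
#'
#' @param m Feature matrix.
#' @param labels Binary labels (0/1).
#' @param params A [hyperParams()].
#' @param fset Feature set (list with `features`, or character vector).
#' @param seed Integer seed.
#' @param encoder Encoder specification recorded in the bundle: list with
#'   `name`, `parts`, `dpcDenominator`.
#' @return A [ModelBundle-class].
#' @export
trainFinal <- function(m, labels, params, fset = colnames(m), seed = 1L,
                       encoder = list(name = "dpc", parts = NULL,
                                      dpcDenominator = "length")) {
  labels <- as.integer(labels)
  if (nrow(m) != length(labels)) stop("matrix rows must match labels")
  ms <- subsetMatrix(m, fset)
  y <- factor(labels, levels = c(0L, 1L))
  model <- .fitModel(params$algorithm, ms, y, params, mixSeed(seed))
  encoder$version <- ENCODER_VERSION
  new("ModelBundle", algorithm = params$algorithm,
      params = unclass(params)[setdiff(names(params), "algorithm")],
      features = colnames(ms), cutoff = 0.5,
      classOrder = c("0", "1"), model = model, encoder = encoder,
      fingerprint = matrixFingerprint(ms),
      version = as.character(packageVersion("aipkit")))
}

#' @rdname ModelBundle-class
#' @export
setMethod("bundleAlgorithm", "ModelBundle", function(x) x@algorithm)

#' @rdname ModelBundle-class
#' @export
setMethod("bundleParams", "ModelBundle", function(x) x@params)

#' @rdname ModelBundle-class
#' @export
setMethod("bundleFeatures", "ModelBundle", function(x) x@features)

#' @rdname ModelBundle-class
#' @export
setMethod("bundleCutoff", "ModelBundle", function(x) x@cutoff)

setMethod("show", "ModelBundle", function(object) {
  cat("ModelBundle:", object@algorithm, "on", length(object@features),
      "features\n")
  p <- object@params
  cat("  params:", paste(names(p), unlist(p), sep = "=", collapse = ", "),
      "\n")
  cat("  cutoff:", object@cutoff, "| encoder:", object@encoder$name,
      "| version:", object@version, "\n")
})

#' Persist / restore a model bundle
#'
#' Serialization is bit-faithful: a reloaded bundle produces identical
#' probabilities.
#'
#' @param bundle A [ModelBundle-class].
#' @param path File path (RDS).
#' @export
saveBundle <- function(bundle, path) {
  stopifnot(is(bundle, "ModelBundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname saveBundle
#' @export
loadBundle <- function(path) {
  bundle <- readRDS(path)
  if (!is(bundle, "ModelBundle")) stop("not a ModelBundle: ", path)
  validObject(bundle)
  bundle
}

#' Tune the probability cutoff on out-of-fold scores
#'
#' Scans a cutoff grid (default 0.01..0.99 step 0.01, built by integer
#' stepping) and returns the cutoff maximizing the MCC of the thresholded
#' out-of-fold predictions (call positive when score `>=` cutoff). Ties are
#' broken toward the cutoff closest to 0.5, then the smaller one. With the
#' class imbalance handled only through this cutoff, an imbalanced dataset
#' typically tunes away from 0.5.
#'
#' @param scores Out-of-fold positive-class probabilities in `[0, 1]`.
#' @param labels Binary labels (0/1).
#' @param gridStep Cutoff grid step (default 0.01).
#' @return The selected cutoff.
#' @export
tuneCutoff <- function(scores, labels, gridStep = 0.01) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores must match labels")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (length(unique(scores)) == 1L) {
    warning("all scores identical; returning cutoff 0.5")
    return(0.5)
  }
  nSteps <- round((0.99 - 0.01) / gridStep)
  cutoffs <- 0.01 + gridStep * (0:nSteps)
  mccs <- vapply(cutoffs, function(ct) {
    thresholdMetrics(confusionCounts(labels, as.integer(scores >= ct)))$mcc
  }, numeric(1))
  best <- which(mccs >= max(mccs) - 1e-12)
  ties <- cutoffs[best]
  ties <- ties[abs(ties - 0.5) <= min(abs(ties - 0.5)) + 1e-12]
  min(ties)
}

#' Predict class probabilities and calls for a peptide dataset
#'
#' Re-encodes the dataset with the bundle's encoder specification, checks
#' the encoder version tag (silent feature misalignment being the main
#' failure mode of serialized sequence models), and returns per-record
#' positive-class probabilities and class calls (positive iff probability
#' `>=` cutoff), preserving input order.
#'
#' @param object A [ModelBundle-class].
#' @param newdata A [PeptideSet-class], or a feature matrix containing the
#'   bundle's features.
#' @param ... Ignored.
#' @return Data frame with columns `id`, `probability`, `class`,
#'   `cutoff_used`.
#' @export
setMethod("predict", "ModelBundle", function(object, newdata, ...) {
  if (!identical(object@encoder$version, ENCODER_VERSION))
    stop("bundle was built with encoder version '", object@encoder$version,
         "' but this package provides '", ENCODER_VERSION,
         "'; retrain before predicting")
  m <- if (is(newdata, "PeptideSet")) {
    encodeDataset(newdata, object@encoder$name,
                  parts = if (is.null(object@encoder$parts)) HYBRID_ORDER
                          else object@encoder$parts,
                  denominator = object@encoder$dpcDenominator %||% "length")
  } else if (is.matrix(newdata)) newdata else
    stop("newdata must be a PeptideSet or a feature matrix")
  ms <- subsetMatrix(m, object@features)
  prob <- .predictProb(object@algorithm, object@model, ms)
  data.frame(id = rownames(ms), probability = unname(prob),
             class = as.integer(prob >= object@cutoff),
             cutoff_used = object@cutoff, stringsAsFactors = FALSE)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' End-to-end training pipeline
#'
#' Executes the full protocol on a labeled dataset: encode, estimate FIS
#' with cross-validated forests, sweep FIS cutoffs into candidate feature
#' sets, grid-search each set with repeated stratified cross-validation,
#' select the set with the highest mean AUC (ties toward the larger set),
#' form consensus (median) parameters, train the final model on the full
#' data and tune the probability cutoff on out-of-fold scores.
#'
#' @param dataset A labeled [PeptideSet-class].
#' @param encoder Encoder id (default `"dpc"`, the composition the
#'   protocol selects features from).
#' @param algorithm Classifier family.
#' @param grid Hyperparameter grid (see [defaultGrid()]).
#' @param folds,repeats CV plan for the per-set grid search.
#' @param fisFolds,fisTrees,mtryLow,mtryHigh FIS estimation settings (see
#'   [estimateFIS()]).
#' @param cutoffLow,cutoffHigh,cutoffStep,fisFloor Sweep settings (see
#'   [generateFeatureSets()]).
#' @param cutoffGridStep Probability-cutoff grid step for [tuneCutoff()].
#' @param seed Master seed; every stage derives sub-seeds from it.
#' @param verbose Print stage progress.
#' @return List with `bundle` (the final [ModelBundle-class]), `sweep`
#'   (data frame: cutoff, n_features, mean_auc, sd_auc per candidate set),
#'   `fis`, `selected` (index of the chosen set), `consensus` and `oof`
#'   (out-of-fold scores used for cutoff tuning).
#' @export
runPipeline <- function(dataset, encoder = "dpc",
                        algorithm = c("RF", "ERT", "SVM", "KNN"),
                        grid = defaultGrid(algorithm),
                        folds = 5L, repeats = 10L,
                        fisFolds = 5L, fisTrees = 10000L,
                        mtryLow = 1L, mtryHigh = 50L,
                        cutoffLow = 0.0005, cutoffHigh = 0.0039,
                        cutoffStep = 0.0001, fisFloor = 0.0005,
                        cutoffGridStep = 0.01, seed = 1L, verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  say <- function(...) if (verbose) message(...)

  labels <- stage("labels", {
    lab <- peptideLabels(dataset)
    if (anyNA(lab)) stop("dataset must be fully labeled")
    as.integer(lab)
  })
  say("encoding (", encoder, ") ...")
  m <- stage("encode", encodeDataset(dataset, encoder))
  say("estimating FIS ...")
  fis <- stage("fis", estimateFIS(m, labels, folds = fisFolds,
                                  nTrees = fisTrees, mtryLow = mtryLow,
                                  mtryHigh = mtryHigh,
                                  seed = mixSeed(seed, 11L)))
  sets <- stage("sweep", generateFeatureSets(fis, cutoffLow, cutoffHigh,
                                             cutoffStep, fisFloor))
  plan <- cvPlan(folds = folds, repeats = repeats,
                 seed = mixSeed(seed, 23L))
  sweepRows <- vector("list", length(sets))
  perSetBest <- vector("list", length(sets))
  for (s in seq_along(sets)) {
    say("grid search on set ", s, "/", length(sets), " (",
        length(sets[[s]]$features), " features) ...")
    gs <- stage("grid_search",
                gridSearch(subsetMatrix(m, sets[[s]]), labels, algorithm,
                           grid, plan))
    perSetBest[[s]] <- gs$best
    sweepRows[[s]] <- data.frame(cutoff = sets[[s]]$cutoff,
                                 n_features = length(sets[[s]]$features),
                                 mean_auc = mean(gs$metrics$auc),
                                 sd_auc = sd(gs$metrics$auc))
  }
  sweep <- do.call(rbind, sweepRows)
  rownames(sweep) <- NULL
  # highest mean AUC; ties toward the larger (lower-cutoff) set
  sel <- order(-sweep$mean_auc, -sweep$n_features)[1L]
  say("selected set ", sel, " (cutoff ", sweep$cutoff[sel], ", ",
      sweep$n_features[sel], " features)")
  consensus <- stage("consensus", consensusParams(perSetBest[[sel]], grid))
  ms <- subsetMatrix(m, sets[[sel]])
  say("training final ", algorithm, " model ...")
  bundle <- stage("train_final",
                  trainFinal(m, labels, consensus, sets[[sel]],
                             seed = mixSeed(seed, 31L),
                             encoder = list(name = encoder, parts = NULL,
                                            dpcDenominator = "length")))
  oofFold <- makeFolds(nrow(ms), labels,
                       cvPlan(folds = folds, repeats = 1L,
                              seed = mixSeed(seed, 37L)))[[1L]]
  oof <- stage("tune_cutoff",
               .oofProbs(ms, factor(labels, levels = c(0L, 1L)), oofFold,
                         algorithm, consensus, mixSeed(seed, 41L)))
  bundle@cutoff <- stage("tune_cutoff",
                         tuneCutoff(oof, labels, cutoffGridStep))
  list(bundle = bundle, sweep = sweep, fis = fis, selected = sel,
       consensus = consensus, oof = oof)
}
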
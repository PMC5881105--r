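test_that("stratified folds hit exact class counts and are reproducible", {
  lab <- rep(c(1L, 0L), c(40L, 60L))
  plan <- cvPlan(folds = 5, repeats = 1, seed = 7)
  f <- makeFolds(100, lab, plan)[[1]]
  for (k in 1:5) {
    expect_equal(sum(lab[f == k] == 1L), 8L)
    expect_equal(sum(lab[f == k] == 0L), 12L)
  }
  expect_identical(makeFolds(100, lab, plan), makeFolds(100, lab, plan))
  # every record in exactly one test fold per repeat
  reps <- makeFolds(100, lab, cvPlan(folds = 5, repeats = 10, seed = 7))
  for (r in reps) expect_true(all(r %in% 1:5) && length(r) == 100)
  # repeats give (essentially always) distinct partitions
  expect_gte(length(unique(lapply(reps, paste, collapse = ""))), 9L)
  expect_error(makeFolds(6, rep(c(1L, 0L), c(3L, 3L)),
                         cvPlan(folds = 4, repeats = 1)), "fewer members")
})

test_that("grid search returns the only point of a 1-point grid and sane AUCs", {
  ds <- generatePeptides(100, 100, defaultProfiles("figure1_strong"),
                         seed = 601)
  m <- encodeDataset(ds, "dpc")
  lab <- peptideLabels(ds)
  gs <- gridSearch(m, lab, "RF", grid = tinyGrid,
                   plan = cvPlan(folds = 3, repeats = 2, seed = 601))
  expect_length(gs$best, 2L)
  for (b in gs$best) {
    expect_equal(b$ntree, tinyGrid$ntree)
    expect_equal(b$mtry, tinyGrid$mtry)
  }
  # separable synthetic data: strong out-of-fold AUC
  expect_gte(mean(gs$metrics$auc), 0.95)
  # permuted labels: chance-level AUC
  set.seed(601)
  gs0 <- gridSearch(m, sample(lab), "RF", grid = tinyGrid,
                    plan = cvPlan(folds = 5, repeats = 1, seed = 602))
  expect_gte(mean(gs0$metrics$auc), 0.4)
  expect_lte(mean(gs0$metrics$auc), 0.6)
  expect_error(gridSearch(m, lab, "RF", grid = list()), "non-empty")
})

test_that("consensus parameters are medians snapped to the grid", {
  hp <- function(nt) hyperParams("RF", ntree = nt, mtry = 1, nsplit = 2)
  same <- consensusParams(list(hp(430), hp(430), hp(430)))
  expect_equal(same$ntree, 430)
  odd <- consensusParams(list(hp(430), hp(410), hp(450)))
  expect_equal(odd$ntree, 430)
  even <- consensusParams(list(hp(410), hp(450)), defaultGrid("RF"))
  expect_equal(even$ntree, 430)
  expect_error(consensusParams(list(hp(430),
                                    hyperParams("KNN", k = 3))), "mixed")
  expect_error(hyperParams("KNN", ntree = 5), "not used")
})

test_that("final models serialize with bit-identical predictions", {
  ds <- generatePeptides(60, 60, defaultProfiles("figure1_strong"),
                         seed = 603)
  m <- encodeDataset(ds, "dpc")
  lab <- peptideLabels(ds)
  bundle <- trainFinal(m, lab, hyperParams("RF", ntree = 150, mtry = 10,
                                           nsplit = 2), seed = 603)
  holdout <- generatePeptides(20, 20, defaultProfiles("figure1_strong"),
                              seed = 604)
  p1 <- predict(bundle, holdout)
  f <- tempfile(fileext = ".rds")
  saveBundle(bundle, f)
  p2 <- predict(loadBundle(f), holdout)
  expect_identical(p1, p2)
  # planted-signal sanity: training-set ranking is near-perfect
  pTrain <- predict(bundle, m)
  expect_gt(rocAuc(pTrain$probability, lab)$auc, 0.99)
})

test_that("every algorithm family trains, predicts and round-trips", {
  ds <- generatePeptides(40, 40, defaultProfiles("figure1_strong"),
                         seed = 605)
  m <- encodeDataset(ds, "aac")
  lab <- peptideLabels(ds)
  params <- list(hyperParams("RF", ntree = 100, mtry = 4, nsplit = 2),
                 hyperParams("ERT", ntree = 100, mtry = 4, nsplit = 2),
                 hyperParams("SVM", cost = 1, gamma = 0.05),
                 hyperParams("KNN", k = 5))
  for (p in params) {
    b <- trainFinal(m, lab, p, seed = 605,
                    encoder = list(name = "aac", parts = NULL,
                                   dpcDenominator = "length"))
    preds <- predict(b, ds)
    expect_equal(nrow(preds), length(ds))
    expect_true(all(preds$probability >= 0 & preds$probability <= 1))
    expect_identical(preds$id, peptideIds(ds))
  }
  # ERT differs from RF by configuration: full sample, random splits
  bert <- trainFinal(m, lab, params[[2]], seed = 605)
  expect_equal(bert@model$splitrule, "extratrees")
  expect_false(bert@model$replace)
  brf <- trainFinal(m, lab, params[[1]], seed = 605)
  expect_equal(brf@model$splitrule, "gini")
  # SVM without probability calibration refuses to predict probabilities
  bs <- trainFinal(m, lab, hyperParams("SVM", cost = 1, gamma = 0.05,
                                       probability = FALSE), seed = 605,
                   encoder = list(name = "aac", parts = NULL,
                                  dpcDenominator = "length"))
  expect_error(predict(bs, ds), "probability")
})

test_that("cutoff tuning maximizes MCC with the documented tie rules", {
  # separable scores: the 0.5-proximity tie rule fires
  expect_equal(tuneCutoff(c(0.9, 0.95, 0.1, 0.05), c(1, 1, 0, 0)), 0.5)
  expect_equal(tuneCutoff(c(0.8, 0.2), c(1, 0)), 0.5)
  expect_warning(ct <- tuneCutoff(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)),
                 "identical")
  expect_equal(ct, 0.5)
  # imbalanced overlapping scores: matches a brute-force oracle, below 0.5
  set.seed(7)
  scores <- c(pmin(pmax(rnorm(40, 0.45, 0.15), 0.01), 0.99),
              pmin(pmax(rnorm(60, 0.30, 0.15), 0.01), 0.99))
  lab <- rep(c(1L, 0L), c(40L, 60L))
  ct <- tuneCutoff(scores, lab)
  cuts <- seq(0.01, 0.99, by = 0.01)
  mccs <- vapply(cuts, function(c0)
    mccOracle(sum(lab == 1 & scores >= c0), sum(lab == 1 & scores < c0),
              sum(lab == 0 & scores < c0), sum(lab == 0 & scores >= c0)),
    numeric(1))
  best <- cuts[mccs >= max(mccs) - 1e-12]
  best <- best[abs(best - 0.5) <= min(abs(best - 0.5)) + 1e-12]
  expect_equal(ct, min(best))
  expect_lt(ct, 0.5)
})

test_that("prediction applies the >= cutoff boundary convention", {
  # 1-d KNN stub: the 5 nearest neighbours of 0 contain exactly 2 positives
  train <- matrix(c(0, 0.1, 0.2, 5, 5.1, 0.05, 0.15), ncol = 1,
                  dimnames = list(NULL, "f"))
  cl <- factor(c(1, 1, 0, 0, 0, 0, 0), levels = c(0, 1))
  bundle <- new("ModelBundle", algorithm = "KNN",
                params = list(k = 5), features = "f", cutoff = 0.4,
                classOrder = c("0", "1"),
                model = list(train = train, cl = cl, k = 5, seed = 1),
                encoder = list(name = "aac", parts = NULL,
                               dpcDenominator = "length",
                               version = aipkit:::ENCODER_VERSION),
                fingerprint = "x", version = "0")
  newx <- matrix(0.08, ncol = 1, dimnames = list("q1", "f"))
  p <- predict(bundle, newx)
  expect_equal(p$probability, 0.4)
  expect_equal(p$class, 1L)     # probability == cutoff: positive
  bundle@cutoff <- 0.401
  expect_equal(predict(bundle, newx)$class, 0L)
  # encoder version mismatch refuses to predict
  bundle@encoder$version <- "other"
  expect_error(predict(bundle, newx), "encoder version")
})

test_that("pipeline selects a top set, reruns identically, rejects unlabeled", {
  ds <- generatePeptides(80, 80, defaultProfiles("figure1_strong"),
                         seed = 607)
  run <- function() runPipeline(ds, folds = 3, repeats = 2, fisFolds = 3,
                                fisTrees = 150,
                                grid = list(ntree = 100L, mtry = 5L,
                                            nsplit = 2L),
                                cutoffStep = 0.0017, seed = 607)
  r1 <- run()
  expect_s4_class(r1$bundle, "ModelBundle")
  expect_true(all(r1$sweep$mean_auc[r1$selected] >=
                  r1$sweep$mean_auc - 0.01))
  r2 <- run()
  expect_identical(r1$sweep, r2$sweep)
  expect_identical(bundleFeatures(r1$bundle), bundleFeatures(r2$bundle))
  expect_identical(bundleCutoff(r1$bundle), bundleCutoff(r2$bundle))
  unl <- PeptideSet(c(u1 = "KLKLK", u2 = "ACDEF"))
  expect_error(runPipeline(unl, fisTrees = 50),
               "stage 'labels'.*labeled")
})

test_that("median CV AUC never decreases along the effect-size ladder", {
  uni <- setNames(rep(1, 20), AAS)
  posW <- uni; posW[c("L", "K", "R")] <- 2
  negW <- uni; negW[c("D", "G", "V", "Y", "P")] <- 2
  med <- vapply(c(0, 0.5, 1), function(e) {
    aucs <- vapply(1:3, function(s) {
      prof <- makeProfile(posW, negW, effectSize = e)
      ds <- generatePeptides(80, 80, prof, seed = 700 + s)
      gs <- gridSearch(encodeDataset(ds, "aac"), peptideLabels(ds), "RF",
                       grid = list(ntree = 100L, mtry = 4L, nsplit = 2L),
                       plan = cvPlan(folds = 3, repeats = 1,
                                     seed = 700 + s))
      mean(gs$metrics$auc)
    }, numeric(1))
    median(aucs)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})
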
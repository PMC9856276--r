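test_that("ROC AUC follows the Mann-Whitney pairwise identity", {
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(rocAuc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(rocAuc(c(0.6, 0.4, 0.2, 0.9), c(0, 1, 0, 1)), 0.75)
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(20)
  for (i in 1:5) {
    sc <- rnorm(30)
    lab <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    a <- rocAuc(sc, lab)
    expect_equal(rocAuc(exp(sc), lab), a)
    expect_equal(rocAuc(2 * sc + 7, lab), a)
    expect_equal(rocAuc(plogis(sc), lab), a)
  }
})

test_that("permutation p uses the add-one estimator with a 1/(B+1) floor", {
  set.seed(21)
  scores <- c(rnorm(10, 5), rnorm(10, -5))   # perfectly separated
  labels <- rep(c("case", "control"), each = 10)
  expect_equal(permutationPvalue(scores, labels, B = 9999, seed = 1), 1e-4)
  expect_equal(permutationPvalue(scores, labels, B = 99, seed = 1), 0.01)
  # deterministic under seed
  sc2 <- rnorm(40); lb2 <- rep(c("case", "control"), 20)
  expect_identical(permutationPvalue(sc2, lb2, B = 199, seed = 7),
                   permutationPvalue(sc2, lb2, B = 199, seed = 7))
})

test_that("bootstrap CI concentrates for separated data and degenerates at B=1", {
  set.seed(22)
  scores <- c(rnorm(100, 4), rnorm(100, -4))
  labels <- rep(c("case", "control"), each = 100)
  ci <- aucCI(scores, labels, nBootstrap = 500, seed = 2)
  expect_gt(ci["ciLow"], 0.95)
  ci1 <- aucCI(scores, labels, nBootstrap = 1, seed = 2)
  expect_equal(unname(ci1["ciLow"]), unname(ci1["ciHigh"]))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  sc <- rnorm(50); lab <- sample(c("case", "control"), 50, replace = TRUE)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(
    response = lab, predictor = sc, levels = c("control", "case"),
    direction = "<"))))
  expect_equal(rocAuc(sc, lab), ref, tolerance = 1e-12)
})

test_that("subset fitness equals an independently coded CV logistic AUC", {
  pe <- makePE(60, 8, seed = 24)
  X <- proteinValues(pe)
  case <- sampleData(pe)$status == "case"
  set.seed(1)
  folds <- proteoPanel:::.stratifiedFolds(case, 5)
  subset <- c("P002", "P004", "P007")
  expect_equal(subsetFitness(X, case, subset, folds),
               cvLogisticOracle(X, case, subset, folds), tolerance = 1e-10)
})

test_that("annealing ranks a perfectly separating protein first", {
  set.seed(25)
  n <- 100
  status <- rep(c("case", "control"), each = n / 2)
  m <- matrix(rnorm(n * 11), n, 11,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("P%02d", 1:11)))
  m[, "P01"] <- ifelse(status == "case", 3, -3) + rnorm(n, 0, 0.1)
  pe <- ProteinExperiment(m, sampleData = data.frame(
    sample_id = rownames(m), status = status), transformState = "standardized")
  rk <- saRankProteins(pe, nIterations = 300, subsetRange = c(2, 6), seed = 3)
  expect_identical(topProteins(rk, 1), "P01")
  expect_identical(unname(proteinRanks(rk)["P01"]), 1L)
  # defaults follow the published settings
  expect_identical(formals(saRankProteins)$nIterations, 1000)
  expect_error(saRankProteins(pe, nIterations = 0), "nIterations")
})

test_that("ranking invariants hold and counts respect iteration bounds", {
  pe <- makePE(50, 12, seed = 26)
  rk <- saRankProteins(pe, nIterations = 60, subsetRange = c(3, 8), seed = 9)
  expect_true(all(selectionCounts(rk) <= rk@nIterations))
  r <- sort(unique(proteinRanks(rk)))
  expect_identical(r, seq_along(r))   # dense ranks
  expect_identical(selectionCounts(saRankProteins(pe, nIterations = 60,
                                                  subsetRange = c(3, 8),
                                                  seed = 9)),
                   selectionCounts(rk))   # deterministic under seed
})

test_that("panel classifiers train on exactly the top-N proteins", {
  set.seed(27)
  n <- 80
  status <- rep(c("case", "control"), each = n / 2)
  m <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("P%02d", 1:5)))
  m[, "P01"] <- ifelse(status == "case", 2, -2)
  pe <- ProteinExperiment(m, sampleData = data.frame(
    sample_id = rownames(m), status = status), transformState = "standardized")
  rk <- saRankProteins(pe, nIterations = 100, subsetRange = c(2, 4), seed = 2)
  clf1 <- buildPanelClassifier(pe, rk, N = 1, ntree = 100, seed = 5)
  expect_identical(panelMembers(clf1), "P01")
  expect_equal(oobAccuracy(clf1), 1.0)

  clfAll <- buildPanelClassifier(pe, rk, N = 5, ntree = 100, seed = 5)
  expect_setequal(panelMembers(clfAll), proteinIds(pe))

  # determinism: same seed, identical predicted probabilities
  a <- buildPanelClassifier(pe, rk, N = 3, ntree = 100, seed = 6)
  b <- buildPanelClassifier(pe, rk, N = 3, ntree = 100, seed = 6)
  expect_identical(predict(a@forest, type = "prob"),
                   predict(b@forest, type = "prob"))
  expect_error(buildPanelClassifier(pe, rk, N = 0), "N must be >= 1")
})

test_that("the panel-size sweep is exhaustive and rebuild-reproducible", {
  pe <- makePE(60, 10, seed = 28)
  rk <- saRankProteins(pe, nIterations = 50, subsetRange = c(3, 6), seed = 1)
  sw <- sweepPanelSizes(pe, rk, nMin = 2, nMax = 6, ntree = 50, seed = 40)
  expect_length(sw, 5L)
  acc <- attr(sw, "accuracies")
  for (i in seq_along(sw)) {
    rebuilt <- buildPanelClassifier(pe, rk, N = acc$N[i], ntree = 50,
                                    seed = 40 + acc$N[i])
    expect_identical(oobAccuracy(rebuilt), acc$oobAccuracy[i])
  }
  one <- sweepPanelSizes(pe, rk, nMin = 5, nMax = 5, ntree = 50)
  expect_length(one, 1L)
})

test_that("modality evaluation honors the missing-panel-protein policy", {
  pe <- makePE(80, 10, seed = 29)
  rk <- saRankProteins(pe, nIterations = 50, subsetRange = c(3, 8), seed = 1)
  clf <- buildPanelClassifier(pe, rk, N = 8, ntree = 100, seed = 3)
  full <- evaluateOnModality(clf, pe)
  expect_true(all(full >= 0 & full <= 1))
  expect_length(attr(full, "missingProteins"), 0L)

  reduced <- pe[setdiff(proteinIds(pe), panelMembers(clf)[1:2]), ]
  dropped <- evaluateOnModality(clf, reduced, missingPolicy = "drop-refit")
  expect_setequal(attr(dropped, "missingProteins"), panelMembers(clf)[1:2])
  imputed <- evaluateOnModality(clf, reduced, missingPolicy = "impute-mean")
  expect_length(imputed, 80L)
  expect_error(evaluateOnModality(clf, reduced, missingPolicy = "error"),
               "missing from test")
  none <- pe[setdiff(proteinIds(pe), panelMembers(clf)), ]
  expect_error(evaluateOnModality(clf, none), "all panel proteins absent")
})

test_that("label-permuted evaluation collapses to chance", {
  cfg <- synthConfig(nSamples = c(serum = 300), caseFraction = c(serum = 0.5),
                     nProteins = c(v2 = 40, v3 = 40), nOverlap = 40,
                     nInformative = 5, informativeEffect = 1.0,
                     moduleBlocks = list(), seed = 55)
  pe <- log2AndStandardize(generateCohort(cfg, "serum"))
  rk <- saRankProteins(pe, nIterations = 100, subsetRange = c(3, 10), seed = 2)
  clf <- buildPanelClassifier(pe, rk, N = 5, ntree = 100, seed = 2)
  sc <- evaluateOnModality(clf, pe)
  set.seed(91)
  permuted <- sample(as.character(sampleData(pe)$status))
  expect_lt(abs(rocAuc(sc, permuted) - 0.5), 0.1)
})

test_that("a null sweep yields no Bonferroni-significant panel in most seeds", {
  safe <- 0L
  for (s in 1:5) {
    cfg <- synthConfig(nSamples = c(serum = 300),
                       caseFraction = c(serum = 0.5),
                       nProteins = c(v2 = 40, v3 = 40), nOverlap = 40,
                       informative = data.frame(id = "P0001", effect = 0),
                       moduleBlocks = list(), seed = 700 + s)
    pe <- log2AndStandardize(generateCohort(cfg, "serum"))
    idx <- seq_len(ncol(pe))
    train <- pe[, idx %% 2 == 1]; test <- pe[, idx %% 2 == 0]
    rk <- saRankProteins(train, nIterations = 60, subsetRange = c(3, 10),
                         seed = s)
    sw <- sweepPanelSizes(train, rk, nMin = 3, nMax = 5, ntree = 60, seed = s)
    ps <- vapply(sw, function(clf) {
      sc <- evaluateOnModality(clf, test)   # held out, so null stays null
      permutationPvalue(sc, sampleData(test)$status, B = 199, seed = s)
    }, numeric(1))
    if (min(ps) * length(ps) > 0.05) safe <- safe + 1L
  }
  expect_gte(safe, 4L)
})
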
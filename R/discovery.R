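# stratified fold assignment: shuffles each class, deals round-robin
.stratifiedFolds <- function(case, nFolds) {
  folds <- integer(length(case))
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(case == cl))
    folds[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  folds
}

#' Cross-validated AUC of a logistic model on a protein subset
#'
#' The subset-fitness criterion of the annealing search: an unpenalized
#' logistic regression on the subset is fit on each training fold and the
#' held-out predictions are pooled into a single ROC AUC.
#'
#' @param X samples x proteins numeric matrix.
#' @param case logical case indicator.
#' @param subset column ids or indices of the candidate panel.
#' @param folds integer fold assignment per sample.
#' @return the pooled cross-validated AUC.
#' @export
subsetFitness <- function(X, case, subset, folds) {
  pred <- numeric(length(case))
  Xs <- cbind(1, X[, subset, drop = FALSE])
  for (f in unique(folds)) {
    tr <- folds != f
    fit <- suppressWarnings(stats::glm.fit(Xs[tr, , drop = FALSE],
                                           as.numeric(case[tr]),
                                           family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred[!tr] <- drop(Xs[!tr, , drop = FALSE] %*% beta)
  }
  rocAuc(pred, case)
}

#' Rank proteins by simulated-annealing selection frequency
#'
#' A greedy annealing search over protein subsets: starting from a random
#' subset, each iteration randomly perturbs the current subset (add, remove
#' or swap one protein) and keeps the candidate only if it discriminates
#' cases from controls strictly better, as measured by the stratified
#' cross-validated AUC of a logistic model (\code{\link{subsetFitness}}).
#' Proteins are then ranked by how often they were selected: at each
#' iteration the members of the reigning accepted subset are credited, so
#' proteins that keep their place in good subsets accumulate weight.
#'
#' @param pe a residualized/standardized \linkS4class{ProteinExperiment}
#'   whose \code{colData} has a \code{status} column.
#' @param nIterations perturbation iterations (default 1000).
#' @param subsetRange admissible subset sizes, c(min, max).
#' @param proposalProbs probabilities of the add/remove/swap moves.
#' @param nFolds cross-validation folds for the fitness.
#' @param temperature optional annealing temperature for stochastic
#'   acceptance of worse candidates with probability
#'   \code{exp(delta/temperature)}; 0 (default) is greedy improvement.
#' @param acceptTies accept equal-fitness candidates that are no larger than
#'   the current subset (default TRUE): the search keeps exploring a fitness
#'   plateau with a parsimony bias instead of freezing on the first subset
#'   that reaches it, so uninformative members churn away while the
#'   discriminating core persists. A clearly worse candidate is still
#'   rejected. FALSE gives strict improvement only.
#' @param fitnessTolerance AUC differences at or below this value are
#'   treated as ties (default 0.01): cross-validated AUC carries
#'   fold-to-fold noise well above this scale, so smaller differences are
#'   not evidence of improvement, and treating them as ties lets the
#'   parsimony bias squeeze uninformative hitchhikers out of the subset.
#' @param countMode count protein membership over "accepted" states only
#'   (default) or over all "visited" states.
#' @param seed RNG seed; the run is deterministic under it.
#' @return a \linkS4class{RankedProteins}; dense ranks by descending
#'   selection count, ties sharing a rank.
#' @export
saRankProteins <- function(pe, nIterations = 1000, subsetRange = c(5, 100),
                           proposalProbs = c(add = 0.25, remove = 0.25,
                                             swap = 0.5),
                           nFolds = 5, temperature = 0, acceptTies = TRUE,
                           fitnessTolerance = 0.01,
                           countMode = c("accepted", "visited"), seed = 1) {
  countMode <- match.arg(countMode)
  if (nIterations < 1) stop("nIterations must be >= 1")
  X <- proteinValues(pe)
  p <- ncol(X)
  if (p < subsetRange[1]) stop("fewer proteins than the minimum subset size")
  case <- .isCase(sampleData(pe)$status)
  if (length(unique(case)) < 2L) stop("both classes must be present")
  set.seed(seed %% .Machine$integer.max)
  folds <- .stratifiedFolds(case, nFolds)
  sMin <- subsetRange[1]; sMax <- min(subsetRange[2], p)
  counts <- stats::setNames(integer(p), colnames(X))
  current <- sample.int(p, sample(seq(sMin, sMax), 1L))
  fitCur <- subsetFitness(X, case, current, folds)
  nAcc <- 0L
  for (it in seq_len(nIterations)) {
    size <- length(current)
    move <- sample(c("add", "remove", "swap"), 1L, prob = proposalProbs)
    if (move == "add" && size >= sMax) move <- "swap"
    if (move == "remove" && size <= sMin) move <- "swap"
    cand <- current
    if (move == "add") {
      cand <- c(current, sample(setdiff(seq_len(p), current), 1L))
    } else if (move == "remove") {
      cand <- current[-sample.int(size, 1L)]
    } else {
      cand[sample.int(size, 1L)] <- sample(setdiff(seq_len(p), current), 1L)
    }
    fitCand <- subsetFitness(X, case, cand, folds)
    accept <- if (acceptTies)
      fitCand > fitCur + fitnessTolerance ||
        (fitCand >= fitCur - fitnessTolerance &&
           length(cand) <= length(current))
    else fitCand > fitCur
    if (!accept && temperature > 0)
      accept <- stats::runif(1) < exp((fitCand - fitCur) / temperature)
    if (accept) {
      current <- cand
      fitCur <- fitCand
      nAcc <- nAcc + 1L
    }
    # membership is credited per iteration: to the reigning accepted state
    # ("accepted", so persistently good subsets accumulate weight) or to the
    # proposed candidate regardless of acceptance ("visited")
    if (countMode == "accepted") counts[current] <- counts[current] + 1L
    else counts[cand] <- counts[cand] + 1L
  }
  rk <- stats::setNames(match(-counts, sort(unique(-counts))), names(counts))
  new("RankedProteins", selectionCount = counts, rank = rk,
      nIterations = as.integer(nIterations), nAccepted = nAcc)
}

#' Top-N proteins of a ranking
#'
#' Rank ties are broken by protein id lexicographic order so the top-N set
#' is deterministic.
#'
#' @param ranked a \linkS4class{RankedProteins}.
#' @param N panel size.
#' @return character vector of N protein ids.
#' @export
topProteins <- function(ranked, N) {
  if (N < 1) stop("N must be >= 1")
  if (N > length(ranked@rank)) stop("N exceeds the number of ranked proteins")
  ids <- names(ranked@selectionCount)
  ord <- order(-ranked@selectionCount, ids)
  ids[ord][seq_len(N)]
}

#' Build an N-protein random-forest panel classifier
#'
#' Trains a random forest on exactly the top-N ranked proteins with a
#' class-balanced bootstrap and records the out-of-bag training accuracy.
#'
#' @param pe the training \linkS4class{ProteinExperiment} with status.
#' @param ranked a \linkS4class{RankedProteins} from the same panel.
#' @param N panel size (top-N by rank, ties broken lexicographically).
#' @param ntree number of trees (default 500).
#' @param mtry features per split; default floor(sqrt(N)).
#' @param seed RNG seed; identical seeds give identical forests.
#' @return a \linkS4class{PanelClassifier}.
#' @export
buildPanelClassifier <- function(pe, ranked, N, ntree = 500, mtry = NULL,
                                 seed = 1) {
  members <- topProteins(ranked, N)
  X <- proteinValues(pe)[, members, drop = FALSE]
  y <- factor(ifelse(.isCase(sampleData(pe)$status), "case", "control"),
              levels = .STATUS_LEVELS)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(N)))
  .fitForest(X, y, N = as.integer(N), members = members, ntree = ntree,
             mtry = mtry, seed = seed)
}

.fitForest <- function(X, y, N, members, ntree, mtry, seed) {
  set.seed(seed %% .Machine$integer.max)
  nMin <- min(table(y))
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = ntree, mtry = min(mtry, ncol(X)),
    strata = y, sampsize = c(nMin, nMin))
  oob <- 1 - unname(rf$err.rate[ntree, "OOB"])
  new("PanelClassifier", N = N, members = members, forest = rf,
      trainX = X, trainY = y, oobAccuracy = oob,
      rfParams = list(ntree = ntree, mtry = mtry), seed = as.integer(seed))
}

#' Sweep panel sizes, building one classifier per N
#'
#' Builds a nested family of random-forest classifiers on the top-N ranked
#' proteins for every N in [nMin, nMax] (the published sweep used 1..200)
#' and records each classifier's out-of-bag accuracy.
#'
#' @param pe training \linkS4class{ProteinExperiment}.
#' @param ranked a \linkS4class{RankedProteins}.
#' @param nMin,nMax panel-size range; the list has length nMax - nMin + 1.
#' @param ntree,mtry forest hyperparameters (see
#'   \code{\link{buildPanelClassifier}}).
#' @param seed base seed; classifier for size N uses seed + N so each
#'   rebuild is independently reproducible.
#' @return list of \linkS4class{PanelClassifier}s, one per N, with the
#'   accuracy sweep in \code{attr(, "accuracies")}.
#' @export
sweepPanelSizes <- function(pe, ranked, nMin = 1, nMax = 200, ntree = 500,
                            mtry = NULL, seed = 1) {
  if (nMin > nMax) stop("nMin must be <= nMax")
  if (nMax > length(ranked@rank)) stop("nMax exceeds the ranked protein count")
  Ns <- seq(nMin, nMax)
  out <- lapply(Ns, function(N)
    buildPanelClassifier(pe, ranked, N, ntree = ntree, mtry = mtry,
                         seed = seed + N))
  names(out) <- paste0("N", Ns)
  attr(out, "accuracies") <- data.frame(
    N = Ns, oobAccuracy = vapply(out, oobAccuracy, numeric(1)))
  out
}

#' Score a test modality with a panel classifier
#'
#' Returns per-sample case probabilities. Panel proteins absent from the
#' test matrix are handled per policy: "drop-refit" (default) refits the
#' forest on the shared member subset using the stored training data
#' (mirroring replication panels reduced by cohort-level QC), "impute-mean"
#' fills missing columns with the training means, "error" stops.
#'
#' @param classifier a \linkS4class{PanelClassifier}.
#' @param testPe the test \linkS4class{ProteinExperiment}.
#' @param missingPolicy "drop-refit", "impute-mean" or "error".
#' @return named numeric case-probability scores in [0, 1]; missing panel
#'   members are listed in \code{attr(, "missingProteins")}.
#' @export
evaluateOnModality <- function(classifier, testPe,
                               missingPolicy = c("drop-refit", "impute-mean",
                                                 "error")) {
  missingPolicy <- match.arg(missingPolicy)
  members <- classifier@members
  present <- intersect(members, proteinIds(testPe))
  missing <- setdiff(members, present)
  if (!length(present)) stop("all panel proteins absent from the test matrix")
  Xt <- proteinValues(testPe)
  if (length(missing)) {
    if (missingPolicy == "error")
      stop("panel protein(s) missing from test matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    if (missingPolicy == "drop-refit") {
      classifier <- .fitForest(
        classifier@trainX[, present, drop = FALSE], classifier@trainY,
        N = length(present), members = present,
        ntree = classifier@rfParams$ntree,
        mtry = max(1L, floor(sqrt(length(present)))),
        seed = classifier@seed)
      Xtest <- Xt[, present, drop = FALSE]
    } else {
      mu <- colMeans(classifier@trainX)
      Xtest <- matrix(rep(mu, each = nrow(Xt)), nrow(Xt), length(members),
                      dimnames = list(rownames(Xt), members))
      Xtest[, present] <- Xt[, present]
    }
  } else {
    Xtest <- Xt[, members, drop = FALSE]
  }
  pr <- stats::predict(classifier@forest, newdata = Xtest, type = "prob")
  out <- stats::setNames(pr[, "case"], rownames(Xtest))
  attr(out, "missingProteins") <- missing
  out
}
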
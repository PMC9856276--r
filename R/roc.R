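# coerce labels to logical "is case"; accepts factor/character with
# case/control labels, logical, or 0/1 numeric
.isCase <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  l <- as.character(labels)
  known <- unique(l[!is.na(l)])
  if (all(known %in% .STATUS_LEVELS)) return(l == "case")
  if (length(known) != 2L) stop("labels must be binary")
  l == sort(known)[2L]   # last level = positive class
}

#' ROC area under the curve
#'
#' The Mann-Whitney identity: the probability that a random case outscores a
#' random control, with ties counted one half.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels; "case"/"control", logical, or 0/1.
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.6, 0.4, 0.2, 0.9), c(0, 1, 0, 1))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  case <- .isCase(labels)
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Permutation p-value for an observed AUC
#'
#' Disease labels are randomly permuted B times; the add-one estimator
#' \code{p = (r + 1) / (B + 1)} counts permuted AUCs at or above the
#' observed one, so the smallest attainable p is 1/(B+1) (1e-4 at the
#' default B = 9999-style 10,000-permutation setting).
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param B number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return the permutation p-value.
#' @export
permutationPvalue <- function(scores, labels, B = 10000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  case <- .isCase(labels)
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  obs <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  set.seed(seed %% .Machine$integer.max)
  n <- length(scores)
  exceed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n1)
    aucB <- (sum(r[idx]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    if (aucB >= obs - 1e-12) exceed <- exceed + 1L
  }
  (exceed + 1) / (B + 1)
}

#' Stratified percentile-bootstrap 95\% CI for the AUC
#'
#' Cases and controls are resampled with replacement separately; the 2.5 and
#' 97.5 percentiles of the bootstrap AUC distribution give the interval,
#' clamped to bracket the point estimate. A single bootstrap draw yields a
#' degenerate equal-bound interval.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param nBootstrap number of bootstrap replicates (default 2000).
#' @param seed RNG seed.
#' @return c(ciLow, ciHigh).
#' @export
aucCI <- function(scores, labels, nBootstrap = 2000, seed = 1) {
  case <- .isCase(labels)
  iCase <- which(case); iCtrl <- which(!case)
  if (length(iCase) < 2L || length(iCtrl) < 2L)
    stop("need at least 2 samples per class")
  obs <- rocAuc(scores, labels)
  set.seed(seed %% .Machine$integer.max)
  reps <- vapply(seq_len(nBootstrap), function(b) {
    sc <- c(scores[sample(iCase, replace = TRUE)],
            scores[sample(iCtrl, replace = TRUE)])
    lb <- rep(c(TRUE, FALSE), c(length(iCase), length(iCtrl)))
    rocAuc(sc, lb)
  }, numeric(1))
  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  c(ciLow = min(ci[1], obs), ciHigh = max(ci[2], obs))
}

#' Full ROC evaluation: AUC, permutation p and bootstrap CI
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param nPermutations permutations for the p-value (default 10000).
#' @param nBootstrap bootstrap replicates for the CI (default 2000).
#' @param seed RNG seed.
#' @return an \linkS4class{ROCResult}.
#' @export
evaluateROC <- function(scores, labels, nPermutations = 10000,
                        nBootstrap = 2000, seed = 1) {
  a <- rocAuc(scores, labels)
  p <- permutationPvalue(scores, labels, B = nPermutations, seed = seed)
  ci <- aucCI(scores, labels, nBootstrap = nBootstrap, seed = seed + 1)
  new("ROCResult", auc = a, ciLow = unname(ci[1]), ciHigh = unname(ci[2]),
      pPerm = p, nPermutations = as.integer(nPermutations),
      nBootstrap = as.integer(nBootstrap))
}
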
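#' Composite disease-severity score
#'
#' A per-case composite of motor and cognitive impairment: the equal-weight
#' mean of z(UPDRS III) and z(30 - MoCA), both z-scored across the scorable
#' cases so that higher values mean more severe disease and the score is
#' invariant to affine rescaling of either clinical scale. This composite is
#' a documented substitute construction (the original study defines its
#' score in supplementary material); the weights are configurable.
#'
#' @param md sample metadata data.frame with status, moca and updrs3
#'   columns (or a \linkS4class{ProteinExperiment}).
#' @param weights length-2 weights for the (updrs3, reversed-moca)
#'   components, normalized to sum 1.
#' @return a \linkS4class{SignatureScores}-like named numeric of per-case
#'   scores wrapped as \code{SignatureScores} (method "meanz" over clinical
#'   components), with excluded case ids in \code{attr}-free slot
#'   \code{dropped}.
#' @export
severityScore <- function(md, weights = c(1, 1)) {
  if (methods::is(md, "ProteinExperiment")) md <- sampleData(md)
  key <- if ("sample_id" %in% colnames(md)) md$sample_id else rownames(md)
  isCase <- .isCase(md$status)
  scorable <- isCase & !is.na(md$moca) & !is.na(md$updrs3)
  if (sum(scorable) < 2L) stop("fewer than 2 scorable cases")
  u <- md$updrs3[scorable]
  m <- 30 - md$moca[scorable]
  z <- function(x) if (stats::sd(x) == 0) rep(0, length(x)) else
    (x - mean(x)) / stats::sd(x)
  w <- weights / sum(weights)
  sc <- w[1] * z(u) + w[2] * z(m)
  new("SignatureScores", scores = stats::setNames(sc, key[scorable]),
      method = "meanz", panel = c("updrs3", "moca_reversed"),
      dropped = key[isCase & !scorable])
}

#' Stratify cases by severity
#'
#' The quantile scheme labels the bottom \code{mildFrac} of cases "mild",
#' the top \code{severeFrac} "severe" and the rest "intermediate" (the
#' published split used the bottom 15\% and top 10\%). The median scheme
#' labels the two halves "below"/"above" (odd counts put the middle sample
#' below). Ordering ties are broken by sample id, so strata are exactly
#' reproducible.
#'
#' @param sev a \linkS4class{SignatureScores} from
#'   \code{\link{severityScore}} (or named numeric scores).
#' @param scheme "quantile" or "median".
#' @param mildFrac,severeFrac stratum fractions for the quantile scheme;
#'   must satisfy 0 < f < 1 and mildFrac + severeFrac <= 1.
#' @return data.frame(sample_id, score, stratum).
#' @export
stratifySeverity <- function(sev, scheme = c("quantile", "median"),
                             mildFrac = 0.15, severeFrac = 0.10) {
  scheme <- match.arg(scheme)
  sc <- if (methods::is(sev, "SignatureScores")) scores(sev) else sev
  n <- length(sc)
  ord <- order(sc, names(sc))
  stratum <- character(n)
  if (scheme == "quantile") {
    if (mildFrac <= 0 || mildFrac >= 1 || severeFrac <= 0 || severeFrac >= 1 ||
        mildFrac + severeFrac > 1)
      stop("fractions must be in (0,1) with mildFrac + severeFrac <= 1")
    nMild <- floor(n * mildFrac + 1e-9)
    nSevere <- floor(n * severeFrac + 1e-9)
    stratum[ord] <- c(rep("mild", nMild),
                      rep("intermediate", n - nMild - nSevere),
                      rep("severe", nSevere))
  } else {
    nBelow <- floor(n / 2) + n %% 2   # odd n: middle sample goes below
    stratum[ord] <- c(rep("below", nBelow), rep("above", n - nBelow))
  }
  data.frame(sample_id = names(sc)[ord][order(ord)], score = unname(sc),
             stratum = stratum, stringsAsFactors = FALSE)[
    , c("sample_id", "score", "stratum")]
}

#' Evaluate a classifier sweep within severity strata
#'
#' For each stratum, the swept classifiers are scored on the subset
#' \{stratum cases\} union \{all controls\} and the best panel (by AUC) is
#' reported with its N, AUC, bootstrap CI and permutation p. Empty strata
#' or strata without both classes are skipped with a note.
#'
#' @param classifiers list of \linkS4class{PanelClassifier}s (e.g. from
#'   \code{\link{sweepPanelSizes}}).
#' @param testPe the evaluation \linkS4class{ProteinExperiment}.
#' @param strata data.frame(sample_id, stratum) from
#'   \code{\link{stratifySeverity}} (controls need not appear).
#' @param nPermutations,nBootstrap resampling sizes for the best panel.
#' @param missingPolicy passed to \code{\link{evaluateOnModality}}.
#' @param seed RNG seed.
#' @return data.frame(stratum, n_cases, n_controls, best_N, auc, ci_low,
#'   ci_high, p_perm); skipped strata in \code{attr(, "skipped")}.
#' @export
stratifiedEvaluation <- function(classifiers, testPe, strata,
                                 nPermutations = 10000, nBootstrap = 2000,
                                 missingPolicy = "drop-refit", seed = 1) {
  md <- sampleData(testPe)
  isCase <- .isCase(md$status)
  controls <- sampleIds(testPe)[!isCase]
  rows <- list(); skipped <- character()
  for (s in unique(strata$stratum)) {
    cases <- intersect(strata$sample_id[strata$stratum == s],
                       sampleIds(testPe)[isCase])
    if (!length(cases) || !length(controls)) {
      skipped <- c(skipped, s); next
    }
    sub <- testPe[, c(cases, controls)]
    labels <- c(rep(TRUE, length(cases)), rep(FALSE, length(controls)))
    best <- NULL
    for (clf in classifiers) {
      sc <- evaluateOnModality(clf, sub, missingPolicy = missingPolicy)
      a <- rocAuc(sc, labels)
      if (is.null(best) || a > best$a) best <- list(a = a, sc = sc, N = clf@N)
    }
    roc <- evaluateROC(best$sc, labels, nPermutations = nPermutations,
                       nBootstrap = nBootstrap, seed = seed)
    rows[[s]] <- data.frame(stratum = s, n_cases = length(cases),
                            n_controls = length(controls), best_N = best$N,
                            auc = auc(roc), ci_low = confint95(roc)[1],
                            ci_high = confint95(roc)[2],
                            p_perm = permutationP(roc),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(stratum = character(), n_cases = integer(),
                      n_controls = integer(), best_N = integer(),
                      auc = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p_perm = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
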
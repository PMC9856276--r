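# Wald test for the protein term, one glm.fit per protein with the protein
# in design column 2. Returns beta/se/p/converged per protein.
.waldScan <- function(Y, yvec, covarX, binomial) {
  n <- length(yvec)
  X <- cbind(`(Intercept)` = rep(1, n), protein = rep(0, n), covarX)
  fam <- if (binomial) stats::binomial() else stats::gaussian()
  p <- ncol(Y)
  beta <- se <- pv <- rep(NA_real_, p)
  conv <- rep(FALSE, p)
  for (j in seq_len(p)) {
    X[, 2L] <- Y[, j]
    fit <- suppressWarnings(stats::glm.fit(X, yvec, family = fam))
    cf <- fit$coefficients
    if (is.na(cf[2L])) next
    keep <- !is.na(cf)
    Xw <- X[, keep, drop = FALSE] * sqrt(fit$weights)
    XtWXinv <- tryCatch(chol2inv(chol(crossprod(Xw))),
                        error = function(e) NULL)
    if (is.null(XtWXinv)) next
    dispersion <- if (binomial) 1 else
      sum(fit$weights * fit$residuals^2) / fit$df.residual
    vc <- rep(NA_real_, length(cf))
    vc[keep] <- diag(XtWXinv) * dispersion
    beta[j] <- cf[2L]
    se[j] <- sqrt(vc[2L])
    z <- beta[j] / se[j]
    pv[j] <- if (binomial) 2 * stats::pnorm(-abs(z)) else
      2 * stats::pt(-abs(z), df = fit$df.residual)
    pv[j] <- max(pv[j], 1e-300)   # keep underflow inside (0, 1]
    boundary <- binomial && (abs(beta[j]) > 15 || !fit$converged)
    conv[j] <- fit$converged && !boundary
  }
  data.frame(protein_id = colnames(Y), beta = beta, se = se, p = pv,
             converged = conv, stringsAsFactors = FALSE)
}

.outcomeVector <- function(pe, outcome) {
  md <- sampleData(pe)
  if (outcome == "status") return(as.numeric(.isCase(md$status)))
  if (outcome == "severity") {
    sv <- severityScore(md)
    out <- rep(NA_real_, ncol(pe))
    out[match(names(scores(sv)), sampleIds(pe))] <- scores(sv)
    return(out)
  }
  if (!outcome %in% colnames(md)) stop("no such outcome column: ", outcome)
  as.numeric(md[[outcome]])
}

#' Per-protein GLM differential-regulation scan
#'
#' Fits one generalized linear model per protein: binomial link with disease
#' status as the outcome and protein + covariates as predictors, Gaussian
#' link for continuous outcomes (MoCA, MDS-UPDRS III, or the composite
#' severity score). Wald p-values are Benjamini-Hochberg adjusted across
#' converged fits only; non-convergent or separated fits are flagged and
#' excluded from the adjustment denominator. Samples with a missing outcome
#' or covariate are dropped per scan.
#'
#' @param pe a log2 (or standardized/residualized)
#'   \linkS4class{ProteinExperiment}.
#' @param outcome "status", "moca", "updrs3" or "severity".
#' @param covariates adjustment covariates (default age, sex, cohort);
#'   NULL for an unadjusted scan.
#' @return data.frame(protein_id, outcome, beta, se, p, p_adj, direction,
#'   converged), with the dropped-sample count in \code{attr(, "nDropped")}.
#' @export
proteinGlmScan <- function(pe, outcome = c("status", "moca", "updrs3",
                                           "severity"),
                           covariates = c("age", "sex", "cohort")) {
  outcome <- match.arg(outcome)
  if (transformState(pe) == "raw")
    stop("scan expects log2 (or standardized/residualized) values")
  yAll <- .outcomeVector(pe, outcome)
  md <- sampleData(pe)
  keep <- !is.na(yAll)
  covarX <- NULL
  if (length(covariates)) {
    # constant covariates within the scanned subset are dropped, not fatal
    usable <- covariates[vapply(covariates, function(cv) {
      v <- md[[cv]][keep]
      length(unique(v[!is.na(v)])) > 1L
    }, logical(1))]
    if (length(usable)) {
      d <- .designMatrix(md[keep, , drop = FALSE], usable)
      keep2 <- which(keep)[d$complete]
      keep <- rep(FALSE, length(keep)); keep[keep2] <- TRUE
      covarX <- d$X[, -1L, drop = FALSE]
    }
  }
  Y <- proteinValues(pe)[keep, , drop = FALSE]
  res <- .waldScan(Y, yAll[keep], covarX, binomial = outcome == "status")
  res$outcome <- outcome
  res$p_adj <- NA_real_
  ok <- res$converged & !is.na(res$p)
  res$p_adj[ok] <- bhAdjust(res$p[ok])
  res$direction <- sign(res$beta)
  res <- res[, c("protein_id", "outcome", "beta", "se", "p", "p_adj",
                 "direction", "converged")]
  attr(res, "nDropped") <- sum(!keep)
  attr(res, "nExcludedFromAdjustment") <- sum(!ok)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that all p-values lie in (0, 1] and applies the BH step-up
#' procedure, returning adjusted values in the input order.
#'
#' @param p numeric p-values in (0, 1].
#' @return adjusted p-values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Targeted biomarker panel scan (unadjusted univariate fits)
#'
#' For a curated candidate panel, fits simple univariate regressions per
#' protein and outcome — logistic for disease status, linear for MoCA and
#' MDS-UPDRS III — with no covariates and no multiplicity adjustment (each
#' candidate is an independent hypothesis). Panel proteins absent from the
#' matrix are listed as untested rather than raising an error.
#'
#' @param pe a log2-scale \linkS4class{ProteinExperiment}.
#' @param panel candidate protein ids.
#' @param outcomes outcomes to scan (default status, moca, updrs3).
#' @return data.frame(protein_id, outcome, beta, se, p, direction,
#'   converged); untested ids in \code{attr(, "untested")}.
#' @export
targetedPanelScan <- function(pe, panel,
                              outcomes = c("status", "moca", "updrs3")) {
  if (!length(panel)) stop("panel must be non-empty")
  present <- intersect(panel, proteinIds(pe))
  untested <- setdiff(panel, present)
  sub <- pe[present, ]
  out <- do.call(rbind, lapply(outcomes, function(o) {
    r <- proteinGlmScan(sub, outcome = o, covariates = NULL)
    r$p_adj <- NULL
    r
  }))
  rownames(out) <- NULL
  attr(out, "untested") <- untested
  out
}

#' Significance matrix of a targeted scan
#'
#' Proteins x outcomes character matrix: "+" for a significant positive
#' direction, "-" for significant negative, "." otherwise.
#'
#' @param de a targeted/DE scan data.frame.
#' @param alpha significance level (default 0.05).
#' @param useAdjusted use p_adj instead of p when available.
#' @export
significanceMatrix <- function(de, alpha = 0.05, useAdjusted = FALSE) {
  pcol <- if (useAdjusted && "p_adj" %in% colnames(de)) de$p_adj else de$p
  prot <- unique(de$protein_id)
  outc <- unique(de$outcome)
  m <- matrix(".", length(prot), length(outc), dimnames = list(prot, outc))
  sig <- !is.na(pcol) & pcol < alpha
  m[cbind(match(de$protein_id, prot), match(de$outcome, outc))] <-
    ifelse(sig, ifelse(de$direction > 0, "+", "-"), ".")
  m
}
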
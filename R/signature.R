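# panel submatrix on the log2 scale, Z-standardized per protein; panel
# members missing from the matrix are dropped (with the list returned)
.panelZ <- function(pe, panel) {
  present <- intersect(panel, proteinIds(pe))
  if (!length(present)) stop("no panel protein present in the matrix")
  X <- proteinValues(pe)[, present, drop = FALSE]
  if (transformState(pe) == "raw") X <- log2(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) stop("zero-variance panel protein(s): ",
                          paste(present[sds == 0], collapse = ", "))
  Z <- scale(X)
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  list(Z = Z, present = present, dropped = setdiff(panel, present))
}

#' Mean-Z signature score
#'
#' Each panel protein is Z-standardized on the log2 scale and the per-sample
#' mean over panel members is the score. Standardization makes the score
#' invariant to affine rescaling of any input protein.
#'
#' @param pe a \linkS4class{ProteinExperiment}.
#' @param panel character vector of panel protein ids; members missing from
#'   the matrix are dropped with a record.
#' @return a \linkS4class{SignatureScores} with method "meanz".
#' @export
meanzScore <- function(pe, panel) {
  pz <- .panelZ(pe, panel)
  new("SignatureScores", scores = rowMeans(pz$Z), method = "meanz",
      panel = pz$present, dropped = pz$dropped)
}

#' SVD eigengene signature score
#'
#' The score is the sample coordinate on the first left singular vector of
#' the standardized samples x panel submatrix, scaled to unit sample
#' variance. The arbitrary SVD sign is anchored so the eigengene correlates
#' positively with the mean-Z score of the same panel.
#'
#' @param pe a \linkS4class{ProteinExperiment}.
#' @param panel panel protein ids (>= 2 present required).
#' @return a \linkS4class{SignatureScores} with method "eigengene".
#' @export
eigengeneScore <- function(pe, panel) {
  pz <- .panelZ(pe, panel)
  if (length(pz$present) < 2L) stop("eigengene needs >= 2 panel proteins")
  if (nrow(pz$Z) < 2L) stop("eigengene needs >= 2 samples")
  sv <- svd(pz$Z, nu = 1, nv = 0)
  if (sv$d[1] < .Machine$double.eps^0.5) stop("rank-0 panel submatrix")
  sc <- drop(sv$u[, 1])
  sc <- sc / stats::sd(sc)
  mz <- rowMeans(pz$Z)
  anchor <- sum(sc * mz)
  if (anchor < 0) sc <- -sc
  new("SignatureScores", scores = stats::setNames(sc, rownames(pz$Z)),
      method = "eigengene", panel = pz$present, dropped = pz$dropped)
}

#' Associate a signature score with a clinical outcome
#'
#' Logistic regression for disease status, ordinary linear regression for
#' continuous outcomes (MoCA, MDS-UPDRS III, severity), optionally adjusted
#' for covariates; the slope, Wald SE and p-value of the score term are
#' returned. Complete logistic separation is a flagged error, not a numeric
#' result.
#'
#' @param sig a \linkS4class{SignatureScores} (or named numeric scores).
#' @param md metadata data.frame with a \code{sample_id} column (or row
#'   names) matching the score names.
#' @param outcome outcome column name; "status" uses the binomial link.
#' @param covariates optional covariate column names.
#' @return one-row data.frame(outcome, beta, se, p, n).
#' @export
signatureAssociation <- function(sig, md, outcome, covariates = NULL) {
  sc <- if (methods::is(sig, "SignatureScores")) scores(sig) else sig
  key <- if ("sample_id" %in% colnames(md)) md$sample_id else rownames(md)
  idx <- match(names(sc), key)
  if (anyNA(idx)) stop("scores contain samples absent from metadata")
  md <- md[idx, , drop = FALSE]
  if (!outcome %in% colnames(md)) stop("no such outcome column: ", outcome)
  df <- data.frame(.y = md[[outcome]], .score = sc)
  for (cv in covariates) df[[cv]] <- md[[cv]]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (identical(outcome, "status")) {
    df$.y <- .isCase(df$.y)
    suspect <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w)))
          suspect <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients[".score", ]
    # boundary fits show up as exploded slope/SE, with or without a warning
    if (suspect || !fit$converged || abs(co[1]) > 15 || co[2] > 50)
      stop("complete separation in the logistic fit", call. = FALSE)
  } else {
    fit <- stats::glm(.y ~ ., data = df, family = stats::gaussian())
  }
  co <- summary(fit)$coefficients[".score", ]
  data.frame(outcome = outcome, beta = unname(co[1]), se = unname(co[2]),
             p = unname(co[4]), n = nrow(df), stringsAsFactors = FALSE)
}
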
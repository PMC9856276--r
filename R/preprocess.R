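#' Filter samples by assay-control scale factor
#'
#' Samples whose per-sample scale factor falls outside the acceptance
#' concentration range (default the closed interval [0.4, 2.5], from the
#' assay vendor's experimental-control criteria) are removed. The removal
#' report is stored in \code{metadata()$qcReport}.
#'
#' @param pe a \linkS4class{ProteinExperiment}.
#' @param scaleFactors named numeric, one factor per sample.
#' @param range length-2 acceptance interval, treated as closed.
#' @return the filtered ProteinExperiment.
#' @export
qcFilterSamples <- function(pe, scaleFactors, range = c(0.4, 2.5)) {
  ids <- sampleIds(pe)
  missing <- setdiff(ids, names(scaleFactors))
  if (length(missing))
    stop("missing scale factor for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  sf <- scaleFactors[ids]
  keep <- sf >= range[1] & sf <= range[2]
  report <- data.frame(sample_id = ids[!keep], scale_factor = sf[!keep],
                       reason = ifelse(sf[!keep] < range[1],
                                       "scale factor below range",
                                       "scale factor above range"),
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- pe[, keep]
  S4Vectors::metadata(out)$qcReport <- report
  out
}

#' Log2-transform and Z-score standardize
#'
#' Raw RFU values are log2 transformed and each protein column is centered
#' and scaled to sample standard deviation one (n - 1 denominator).
#'
#' @param pe a raw \linkS4class{ProteinExperiment}.
#' @param onZeroVariance "error" (default) stops naming the offending
#'   protein; "drop" removes zero-variance proteins with a report.
#' @return a standardized ProteinExperiment.
#' @export
log2AndStandardize <- function(pe, onZeroVariance = c("error", "drop")) {
  onZeroVariance <- match.arg(onZeroVariance)
  if (transformState(pe) != "raw")
    stop("log2AndStandardize expects a raw matrix; got ", transformState(pe))
  X <- log2(proteinValues(pe))
  sds <- apply(X, 2L, stats::sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    if (onZeroVariance == "error")
      stop("zero-variance protein(s): ",
           paste(utils::head(colnames(X)[zero], 5), collapse = ", "))
    pe <- pe[!zero, ]
    X <- X[, !zero, drop = FALSE]
    sds <- sds[!zero]
    S4Vectors::metadata(pe)$droppedZeroVariance <- names(which(zero))
  }
  Z <- scale(X, center = TRUE, scale = sds)
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  .setValues(pe, Z, "standardized")
}

#' Log2-transform only
#' @param pe a raw \linkS4class{ProteinExperiment}.
#' @return a log2-scale ProteinExperiment.
#' @export
log2Transform <- function(pe) {
  if (transformState(pe) != "raw")
    stop("log2Transform expects a raw matrix; got ", transformState(pe))
  .setValues(pe, log2(proteinValues(pe)), "log2")
}

# numeric design matrix from named covariates; dates become days since the
# earliest date, factors are dummy-coded with the alphabetically first level
# as reference
.designMatrix <- function(md, covariates) {
  cols <- lapply(covariates, function(cv) {
    if (!cv %in% colnames(md)) stop("covariate not in metadata: ", cv)
    v <- md[[cv]]
    if (inherits(v, "Date")) v <- as.numeric(v - min(v, na.rm = TRUE))
    v
  })
  names(cols) <- covariates
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  for (cv in covariates) {
    if (is.character(df[[cv]]))
      df[[cv]] <- factor(df[[cv]], levels = sort(unique(df[[cv]])))
    if (is.factor(df[[cv]])) df[[cv]] <- droplevels(df[[cv]])
    v <- df[[cv]]
    if ((is.factor(v) && nlevels(v) < 2L) ||
        (is.numeric(v) && stats::sd(v, na.rm = TRUE) == 0))
      stop("covariate constant across samples: ", cv)
  }
  complete <- stats::complete.cases(df)
  X <- stats::model.matrix(~ ., data = df[complete, , drop = FALSE])
  list(X = X, complete = complete)
}

#' Residualize protein expression on covariates
#'
#' Each protein is replaced by the residuals of an ordinary least-squares
#' fit (a Gaussian-link GLM) of its log2/standardized expression on the
#' named covariates. Samples with missing covariate values are dropped and
#' reported in \code{metadata()$residualizeReport}.
#'
#' @param pe a log2 or standardized \linkS4class{ProteinExperiment}.
#' @param covariates character vector of \code{colData} column names; dates
#'   are encoded as days since the earliest date, character columns are
#'   dummy-coded factors (reference = first level alphabetically).
#' @return a residualized ProteinExperiment.
#' @export
residualizeCovariates <- function(pe, covariates) {
  if (!transformState(pe) %in% c("log2", "standardized"))
    stop("residualizeCovariates expects log2 or standardized values")
  d <- .designMatrix(sampleData(pe), covariates)
  if (!all(d$complete)) pe <- pe[, d$complete]
  Y <- proteinValues(pe)
  qrX <- qr(d$X)
  resid <- Y - d$X %*% qr.coef(qrX, Y)
  out <- .setValues(pe, resid, "residualized")
  S4Vectors::metadata(out)$residualizeReport <-
    list(nDroppedMissingCovariates = sum(!d$complete), covariates = covariates)
  out
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Removes per-batch location/scale structure on the log2 scale using the
#' parametric empirical-Bayes ComBat model, while protecting biological
#' covariates (e.g. disease status) through the model matrix. With a single
#' batch the matrix is returned unchanged.
#'
#' @param pe a log2/standardized \linkS4class{ProteinExperiment}.
#' @param batch \code{colData} column naming the batch (default "batch").
#' @param protect covariate names whose effects must be preserved
#'   (default "status").
#' @param meanOnly if TRUE adjust locations only (no scale adjustment).
#' @return the batch-adjusted ProteinExperiment.
#' @export
combatAdjust <- function(pe, batch = "batch", protect = "status",
                         meanOnly = FALSE) {
  md <- sampleData(pe)
  if (!batch %in% colnames(md)) stop("no such batch column: ", batch)
  b <- factor(md[[batch]])
  if (nlevels(b) < 2L) return(pe)
  tab <- table(b)
  if (any(tab < 2L))
    stop("batch(es) with a single sample: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  mod <- NULL
  if (length(protect)) {
    pv <- md[, protect, drop = FALSE]
    for (cv in protect) {
      ct <- table(b, pv[[cv]])
      if (all(rowSums(ct > 0) == 1L))
        stop("batch perfectly confounded with protected covariate: ", cv)
    }
    mod <- stats::model.matrix(~ ., data = pv)
  }
  dat <- t(proteinValues(pe))   # proteins x samples, as ComBat expects
  adj <- sva::ComBat(dat = dat, batch = b, mod = mod, par.prior = TRUE,
                     mean.only = meanOnly, prior.plots = FALSE)
  .setValues(pe, t(adj), transformState(pe))
}

#' Scan principal components for confounder associations
#'
#' Computes the top-k PC scores of the standardized matrix by SVD and tests
#' each PC against each confounder: one-way ANOVA F for categorical
#' variables, Pearson correlation test for numeric ones. Pairs with
#' p below \code{alpha} are flagged.
#'
#' @param pe a \linkS4class{ProteinExperiment} (standardized recommended).
#' @param confounders \code{colData} column names to test.
#' @param k number of leading PCs (0 gives an empty report).
#' @param alpha flagging threshold.
#' @return data.frame(pc, confounder, statistic, p, flagged) plus the
#'   variance explained per PC in \code{attr(, "varExplained")}.
#' @export
pcConfounderScan <- function(pe, confounders, k = 10, alpha = 0.01) {
  empty <- data.frame(pc = integer(), confounder = character(),
                      statistic = numeric(), p = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE)
  if (k == 0) return(empty)
  X <- proteinValues(pe)
  k <- min(k, nrow(X) - 1L, ncol(X))
  ctr <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = k, nv = 0)
  pcs <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  md <- sampleData(pe)
  out <- empty
  for (cv in confounders) {
    if (!cv %in% colnames(md)) stop("confounder not in metadata: ", cv)
    v <- md[[cv]]
    if (inherits(v, "Date")) v <- as.numeric(v)
    for (i in seq_len(k)) {
      ok <- !is.na(v)
      if (is.numeric(v)) {
        ct <- stats::cor.test(pcs[ok, i], v[ok])
        stat <- unname(ct$estimate); p <- ct$p.value
      } else {
        f <- droplevels(factor(v[ok]))
        if (nlevels(f) < 2L) { stat <- NA_real_; p <- 1 }
        else {
          a <- stats::anova(stats::lm(pcs[ok, i] ~ f))
          stat <- a[1, "F value"]; p <- a[1, "Pr(>F)"]
        }
      }
      out <- rbind(out, data.frame(pc = i, confounder = cv, statistic = stat,
                                   p = p, flagged = p < alpha,
                                   stringsAsFactors = FALSE))
    }
  }
  attr(out, "varExplained") <- (sv$d[seq_len(k)]^2) / sum(sv$d^2)
  out
}
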
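#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.TRANSFORM_STATES <- c("raw", "log2", "standardized", "residualized")

#' ProteinExperiment: an expression matrix with per-sample covariates
#'
#' Extends \linkS4class{SummarizedExperiment} with a single assay of protein
#' expression (proteins in rows, samples in columns) and a transform-state
#' flag recording where the values sit in the normalization chain: raw
#' relative fluorescence units (RFU), \code{log2}, per-protein standardized,
#' or covariate-residualized.
#'
#' Raw values must be strictly positive and finite; protein and sample
#' identifiers must be unique. Clinical and technical covariates (disease
#' status, age, sex, cohort, modality, MoCA, MDS-UPDRS III, LEDD, batch,
#' assay/prep dates) live in \code{colData}.
#'
#' @slot transformState character scalar, one of \code{"raw"}, \code{"log2"},
#'   \code{"standardized"}, \code{"residualized"}.
#' @export
setClass("ProteinExperiment",
  contains = "SummarizedExperiment",
  slots = c(transformState = "character"),
  prototype = prototype(transformState = "raw")
)

setValidity("ProteinExperiment", function(object) {
  msgs <- character()
  ts <- object@transformState
  if (length(ts) != 1L || !ts %in% .TRANSFORM_STATES)
    msgs <- c(msgs, sprintf("transformState must be one of %s",
                            paste(.TRANSFORM_STATES, collapse = ", ")))
  if (length(SummarizedExperiment::assays(object)) >= 1L) {
    v <- SummarizedExperiment::assay(object, 1L)
    if (anyDuplicated(rownames(v)))
      msgs <- c(msgs, sprintf("duplicate protein id(s): %s",
        paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
    if (anyDuplicated(colnames(v)))
      msgs <- c(msgs, sprintf("duplicate sample id(s): %s",
        paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
    if (!all(is.finite(v)))
      msgs <- c(msgs, "all expression values must be finite")
    else if (identical(ts, "raw") && any(v <= 0))
      msgs <- c(msgs, "raw RFU values must be strictly positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Selection-frequency ranking of proteins from simulated annealing
#'
#' @slot selectionCount named integer, times each protein appeared in an
#'   accepted subset over the annealing run.
#' @slot rank named integer, dense rank by descending selection count
#'   (ties share a rank).
#' @slot nIterations integer, total annealing iterations run.
#' @slot nAccepted integer, number of accepted moves.
#' @export
setClass("RankedProteins",
  slots = c(selectionCount = "integer", rank = "integer",
            nIterations = "integer", nAccepted = "integer"))

setValidity("RankedProteins", function(object) {
  msgs <- character()
  if (is.null(names(object@selectionCount)))
    msgs <- c(msgs, "selectionCount must be named by protein id")
  if (!identical(names(object@selectionCount), names(object@rank)))
    msgs <- c(msgs, "rank and selectionCount must share names")
  if (any(object@selectionCount > object@nIterations))
    msgs <- c(msgs, "selectionCount cannot exceed nIterations")
  if (length(object@rank) &&
      !setequal(unique(object@rank), seq_len(length(unique(object@rank)))))
    msgs <- c(msgs, "ranks must be a dense 1..k ranking")
  if (length(msgs)) msgs else TRUE
})

#' An N-protein random-forest panel classifier
#'
#' Holds the fitted forest together with the exact training data so that the
#' panel can be refit on a reduced member set when a test matrix lacks some
#' panel proteins (the drop-and-refit policy).
#'
#' @slot N integer panel size.
#' @slot members character, the top-N ranked protein ids.
#' @slot forest the fitted \code{randomForest} object.
#' @slot trainX training matrix (samples x members).
#' @slot trainY training status factor (levels control, case).
#' @slot oobAccuracy out-of-bag training accuracy.
#' @slot rfParams list of forest hyperparameters used.
#' @slot seed integer seed the forest was grown under.
#' @export
setClass("PanelClassifier",
  slots = c(N = "integer", members = "character", forest = "ANY",
            trainX = "matrix", trainY = "factor", oobAccuracy = "numeric",
            rfParams = "list", seed = "integer"))

setValidity("PanelClassifier", function(object) {
  msgs <- character()
  if (object@N < 1L) msgs <- c(msgs, "N must be >= 1")
  if (length(object@members) != object@N)
    msgs <- c(msgs, "members must have length N")
  if (length(msgs)) msgs else TRUE
})

#' ROC evaluation result: AUC with permutation p and bootstrap CI
#'
#' @slot auc area under the ROC curve (Mann-Whitney tie convention).
#' @slot ciLow,ciHigh 95\% stratified percentile-bootstrap bounds.
#' @slot pPerm permutation p-value, add-one estimator (r+1)/(B+1).
#' @slot nPermutations,nBootstrap resampling sizes used (NA if skipped).
#' @export
setClass("ROCResult",
  slots = c(auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
            pPerm = "numeric", nPermutations = "integer",
            nBootstrap = "integer"))

setValidity("ROCResult", function(object) {
  msgs <- character()
  if (object@auc < 0 || object@auc > 1) msgs <- c(msgs, "auc must be in [0,1]")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh)) {
    if (object@ciLow > object@auc + 1e-12 || object@ciHigh < object@auc - 1e-12)
      msgs <- c(msgs, "CI must bracket the AUC")
  }
  if (!is.na(object@pPerm) && !is.na(object@nPermutations) &&
      object@pPerm < 1 / (object@nPermutations + 1) - 1e-12)
    msgs <- c(msgs, "pPerm cannot undercut the 1/(B+1) floor")
  if (length(msgs)) msgs else TRUE
})

#' Per-sample scalar signature scores
#'
#' @slot scores named numeric, one score per sample.
#' @slot method "meanz" or "eigengene".
#' @slot panel protein ids actually used (after dropping absentees).
#' @slot dropped panel ids absent from the matrix.
#' @export
setClass("SignatureScores",
  slots = c(scores = "numeric", method = "character", panel = "character",
            dropped = "character"))

setValidity("SignatureScores", function(object) {
  if (!object@method %in% c("meanz", "eigengene"))
    return("method must be 'meanz' or 'eigengene'")
  if (is.null(names(object@scores))) return("scores must be named by sample")
  TRUE
})

#' Co-expression module set
#'
#' @slot assignment named character protein -> module label; "grey" marks
#'   unassigned proteins.
#' @slot power soft-threshold exponent used for the adjacency.
#' @slot minSize smallest admissible module.
#' @slot eigengenes samples x modules matrix of unit-variance eigengene scores.
#' @slot hubs named character module -> hub protein id.
#' @slot kme proteins x modules matrix of correlations with eigengenes.
#' @export
setClass("ModuleSet",
  slots = c(assignment = "character", power = "numeric", minSize = "integer",
            eigengenes = "matrix", hubs = "character", kme = "matrix"))

setValidity("ModuleSet", function(object) {
  msgs <- character()
  if (is.null(names(object@assignment)))
    msgs <- c(msgs, "assignment must be named by protein id")
  mods <- setdiff(unique(object@assignment), "grey")
  sizes <- table(object@assignment[object@assignment != "grey"])
  if (length(sizes) && any(sizes < object@minSize))
    msgs <- c(msgs, "every non-grey module must have >= minSize members")
  if (ncol(object@eigengenes) > 0 && !all(colnames(object@eigengenes) %in% mods))
    msgs <- c(msgs, "eigengene columns must be module labels")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the synthetic multi-cohort proteomic study
#'
#' Defines the study conditions emulated by the generator: per-modality
#' sample sizes and case fractions, two assay-panel versions with an
#' overlapping protein subset, planted case-associated proteins (log2
#' effects), severity-correlated proteins, correlated co-expression blocks,
#' batch location/scale structure, per-modality effect attenuation, and the
#' measurement noise level on the log2 scale.
#'
#' @export
setClass("SynthConfig",
  slots = c(
    nSamples = "numeric",          # named by modality
    caseFraction = "numeric",      # named by modality
    nProteins = "numeric",         # named by version, e.g. c(v2=, v3=)
    nOverlap = "numeric",
    informative = "data.frame",    # id, effect (log2 case-control)
    severityProteins = "data.frame",  # id, slope vs latent severity
    moduleBlocks = "list",         # list of list(members=, rho=)
    batchSpec = "data.frame",      # label, shift, scale, fraction
    noiseSd = "numeric",
    attenuation = "numeric",       # named by modality, scales effects
    effectSeverityCoupling = "numeric",
    versions = "character",        # named by modality -> panel version
    seed = "numeric"))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (any(object@caseFraction <= 0 | object@caseFraction >= 1))
    msgs <- c(msgs, "caseFraction must be in (0, 1)")
  if (object@nOverlap > min(object@nProteins))
    msgs <- c(msgs, "nOverlap cannot exceed the smallest panel")
  for (b in object@moduleBlocks)
    if (b$rho <= 0 || b$rho >= 1)
      msgs <- c(msgs, "module block correlation must be in (0, 1)")
  if (object@noiseSd <= 0) msgs <- c(msgs, "noiseSd must be > 0")
  if (!all(names(object@nSamples) %in% names(object@versions)))
    msgs <- c(msgs, "every modality needs a panel version")
  if (length(msgs)) msgs else TRUE
})
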
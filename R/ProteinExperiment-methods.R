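#' Construct a ProteinExperiment
#'
#' @param values numeric matrix with samples in rows and proteins in columns
#'   (the layout of a typical proteomics export); stored internally in the
#'   SummarizedExperiment convention (proteins in rows).
#' @param sampleData data.frame or DataFrame of per-sample covariates, one
#'   row per sample in the row order of \code{values}. Optional.
#' @param transformState one of "raw", "log2", "standardized", "residualized".
#' @return a \linkS4class{ProteinExperiment}.
#' @examples
#' m <- matrix(2^rnorm(12, 10), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("P", 1:4)))
#' pe <- ProteinExperiment(m)
#' @export
ProteinExperiment <- function(values, sampleData = NULL,
                              transformState = "raw") {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample (row) and protein (column) names")
  a <- t(values)
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(a))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = a),
    colData = S4Vectors::DataFrame(sampleData, row.names = colnames(a)))
  new("ProteinExperiment", se, transformState = transformState)
}

#' @rdname proteinValues
#' @export
setGeneric("proteinValues", function(x) standardGeneric("proteinValues"))

#' Expression values as a samples-by-proteins matrix
#'
#' @param x a ProteinExperiment.
#' @return numeric matrix, samples in rows, proteins in columns.
#' @export
setMethod("proteinValues", "ProteinExperiment",
          function(x) t(SummarizedExperiment::assay(x, 1L)))

#' @rdname transformState
#' @export
setGeneric("transformState", function(x) standardGeneric("transformState"))

#' Transform state of a ProteinExperiment
#' @param x a ProteinExperiment.
#' @return one of "raw", "log2", "standardized", "residualized".
#' @export
setMethod("transformState", "ProteinExperiment",
          function(x) x@transformState)

#' @rdname proteinIds
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' Protein assay identifiers
#' @param x a ProteinExperiment.
#' @export
setMethod("proteinIds", "ProteinExperiment", function(x) rownames(x))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Sample identifiers
#' @param x a ProteinExperiment.
#' @export
setMethod("sampleIds", "ProteinExperiment", function(x) colnames(x))

#' @rdname sampleData
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' Per-sample covariates as a base data.frame
#' @param x a ProteinExperiment.
#' @export
setMethod("sampleData", "ProteinExperiment",
          function(x) as.data.frame(SummarizedExperiment::colData(x)))

# internal: replace the assay while keeping structure, set new state
.setValues <- function(pe, values, transformState) {
  a <- t(values)
  SummarizedExperiment::assay(pe, 1L, withDimnames = FALSE) <- a
  pe@transformState <- transformState
  methods::validObject(pe)
  pe
}

setMethod("show", "ProteinExperiment", function(object) {
  cat(sprintf("ProteinExperiment: %d proteins x %d samples [%s]\n",
              nrow(object), ncol(object), object@transformState))
  methods::callNextMethod()
})

setMethod("show", "RankedProteins", function(object) {
  top <- names(sort(object@rank))[seq_len(min(5L, length(object@rank)))]
  cat(sprintf("RankedProteins: %d proteins, %d iterations, %d accepted moves\n",
              length(object@rank), object@nIterations, object@nAccepted))
  cat("  top ranked:", paste(top, collapse = ", "), "\n")
})

setMethod("show", "PanelClassifier", function(object) {
  cat(sprintf("PanelClassifier: N = %d, OOB accuracy = %.3f\n",
              object@N, object@oobAccuracy))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.3f (95%% CI %.3f-%.3f), permutation p = %s\n",
              object@auc, object@ciLow, object@ciHigh,
              format(object@pPerm, digits = 3)))
})

setMethod("show", "SignatureScores", function(object) {
  cat(sprintf("SignatureScores [%s]: %d samples, %d panel proteins (%d dropped)\n",
              object@method, length(object@scores), length(object@panel),
              length(object@dropped)))
})

setMethod("show", "ModuleSet", function(object) {
  sizes <- table(object@assignment)
  cat(sprintf("ModuleSet: %d proteins, %d modules (power %g, minSize %d)\n",
              length(object@assignment),
              length(setdiff(names(sizes), "grey")),
              object@power, object@minSize))
  print(sizes)
})

#' Accessors for result objects
#'
#' \code{auc}, \code{permutationP}, \code{confint95} read an
#' \linkS4class{ROCResult}; \code{scores} reads \linkS4class{SignatureScores};
#' \code{moduleAssignment}, \code{moduleEigengeneMatrix}, \code{moduleHubs}
#' read a \linkS4class{ModuleSet}; \code{panelMembers} and \code{oobAccuracy}
#' read a \linkS4class{PanelClassifier}; \code{selectionCounts} and
#' \code{proteinRanks} read a \linkS4class{RankedProteins}.
#'
#' @param x a result object.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @rdname result-accessors
#' @export
setMethod("auc", "ROCResult", function(x) x@auc)

#' @rdname result-accessors
#' @export
setGeneric("permutationP", function(x) standardGeneric("permutationP"))
#' @rdname result-accessors
#' @export
setMethod("permutationP", "ROCResult", function(x) x@pPerm)

#' @rdname result-accessors
#' @export
setGeneric("confint95", function(x) standardGeneric("confint95"))
#' @rdname result-accessors
#' @export
setMethod("confint95", "ROCResult",
          function(x) c(low = x@ciLow, high = x@ciHigh))

#' @rdname result-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname result-accessors
#' @export
setMethod("scores", "SignatureScores", function(x) x@scores)

#' @rdname result-accessors
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))
#' @rdname result-accessors
#' @export
setMethod("moduleAssignment", "ModuleSet", function(x) x@assignment)

#' @rdname result-accessors
#' @export
setGeneric("moduleEigengeneMatrix",
           function(x) standardGeneric("moduleEigengeneMatrix"))
#' @rdname result-accessors
#' @export
setMethod("moduleEigengeneMatrix", "ModuleSet", function(x) x@eigengenes)

#' @rdname result-accessors
#' @export
setGeneric("moduleHubs", function(x) standardGeneric("moduleHubs"))
#' @rdname result-accessors
#' @export
setMethod("moduleHubs", "ModuleSet", function(x) x@hubs)

#' @rdname result-accessors
#' @export
setGeneric("panelMembers", function(x) standardGeneric("panelMembers"))
#' @rdname result-accessors
#' @export
setMethod("panelMembers", "PanelClassifier", function(x) x@members)

#' @rdname result-accessors
#' @export
setGeneric("oobAccuracy", function(x) standardGeneric("oobAccuracy"))
#' @rdname result-accessors
#' @export
setMethod("oobAccuracy", "PanelClassifier", function(x) x@oobAccuracy)

#' @rdname result-accessors
#' @export
setGeneric("selectionCounts", function(x) standardGeneric("selectionCounts"))
#' @rdname result-accessors
#' @export
setMethod("selectionCounts", "RankedProteins", function(x) x@selectionCount)

#' @rdname result-accessors
#' @export
setGeneric("proteinRanks", function(x) standardGeneric("proteinRanks"))
#' @rdname result-accessors
#' @export
setMethod("proteinRanks", "RankedProteins", function(x) x@rank)
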
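# module label palette, assigned by descending module size
.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue")

#' Unsigned adjacency and topological overlap matrix
#'
#' Builds the weighted co-expression network: soft-power adjacency
#' \code{a_ij = |cor(x_i, x_j)|^power} (unsigned, zero diagonal) and the
#' topological overlap measure
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#' with connectivity \code{k_i = sum_j a_ij}, \code{TOM_ii = 1}. The
#' published adaptation fixes the soft power at 2.
#'
#' @param pe a log2/standardized \linkS4class{ProteinExperiment}, or a
#'   samples x proteins matrix.
#' @param power soft-threshold exponent (default 2).
#' @param onConstant "error" (default) or "drop" for zero-variance proteins.
#' @return list(adjacency, tom), both symmetric with entries in [0, 1].
#' @export
adjacencyTom <- function(pe, power = 2, onConstant = c("error", "drop")) {
  onConstant <- match.arg(onConstant)
  X <- if (methods::is(pe, "ProteinExperiment")) proteinValues(pe) else pe
  if (ncol(X) < 3L) stop("need at least 3 proteins")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    if (onConstant == "error")
      stop("constant protein(s): ",
           paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  a <- abs(stats::cor(X, use = "pairwise.complete.obs"))^power
  diag(a) <- 0
  k <- colSums(a)
  L <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2   # symmetrize against rounding
  list(adjacency = a, tom = tom)
}

# eigengene of one member submatrix: first PC of the standardized columns,
# unit sample variance, sign anchored to positive mean member correlation
.moduleEigengene <- function(Z) {
  if (ncol(Z) == 1L) return(drop(scale(Z)))
  sv <- svd(scale(Z), nu = 1, nv = 0)
  e <- drop(sv$u[, 1])
  e <- e / stats::sd(e)
  if (mean(stats::cor(Z, e)) < 0) e <- -e
  e
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' \code{1 - TOM}, cut at a static height; clusters below the minimum size
#' are assigned "grey". For matrices larger than \code{blockSize}, proteins
#' are first pre-clustered into blocks (k-means on the dissimilarity rows,
#' the block-wise step) and modules are detected per block. When the
#' expression matrix is supplied, modules whose eigengenes correlate above
#' \code{mergeCor} are merged. Module labels are colors ordered by
#' descending size.
#'
#' @param tom topological overlap matrix from \code{\link{adjacencyTom}}.
#' @param minSize minimum module size (default 30, per the adapted
#'   proteomic pipeline).
#' @param blockSize maximum proteins clustered at once (default 5000).
#' @param cutHeight static tree-cut height on 1 - TOM (default 0.85).
#' @param pe optional \linkS4class{ProteinExperiment} (or samples x proteins
#'   matrix) enabling the eigengene merge step.
#' @param mergeCor eigengene correlation above which modules merge
#'   (default 0.8).
#' @return named character vector protein -> module label ("grey" =
#'   unassigned).
#' @export
detectModules <- function(tom, minSize = 30, blockSize = 5000,
                          cutHeight = 0.85, pe = NULL, mergeCor = 0.8) {
  if (minSize < 2) stop("minSize must be >= 2")
  if (blockSize < minSize) stop("blockSize must be >= minSize")
  p <- ncol(tom)
  ids <- colnames(tom)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  diss <- 1 - tom
  if (p > blockSize) {
    nBlocks <- ceiling(p / blockSize)
    km <- stats::kmeans(diss, centers = nBlocks, nstart = 3)
    blocks <- split(seq_len(p), km$cluster)
  } else blocks <- list(seq_len(p))
  cl <- integer(p)
  nxt <- 1L
  for (idx in blocks) {
    if (length(idx) < 2L) next
    hc <- stats::hclust(stats::as.dist(diss[idx, idx, drop = FALSE]),
                        method = "average")
    ct <- stats::cutree(hc, h = cutHeight)
    for (g in unique(ct)) {
      mem <- idx[ct == g]
      if (length(mem) >= minSize) { cl[mem] <- nxt; nxt <- nxt + 1L }
    }
  }
  # optional merge of near-identical modules by eigengene correlation
  if (!is.null(pe) && nxt > 2L) {
    X <- if (methods::is(pe, "ProteinExperiment")) proteinValues(pe) else pe
    repeat {
      labs <- setdiff(unique(cl), 0L)
      if (length(labs) < 2L) break
      eg <- vapply(labs, function(l)
        .moduleEigengene(X[, ids[cl == l], drop = FALSE]), numeric(nrow(X)))
      cm <- stats::cor(eg)
      diag(cm) <- 0
      mx <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
      if (cm[mx[1], mx[2]] <= mergeCor) break
      cl[cl == labs[mx[2]]] <- labs[mx[1]]
    }
  }
  sizes <- sort(table(cl[cl > 0]), decreasing = TRUE)
  lab <- rep("grey", p)
  for (i in seq_along(sizes)) {
    col <- if (i <= length(.MODULE_COLORS)) .MODULE_COLORS[i] else
      paste0("module", i)
    lab[cl == as.integer(names(sizes)[i])] <- col
  }
  stats::setNames(lab, ids)
}

#' Module eigengenes, kME and hub proteins
#'
#' Per non-grey module: the eigengene is the first principal component of
#' the standardized member submatrix (unit sample variance, sign anchored
#' to positive mean correlation with members); kME is the correlation of
#' every protein with each eigengene; the hub is the member with the
#' largest |kME| (ties broken by protein id). Size-1 modules degenerate to
#' the member's Z score.
#'
#' @param pe a log2/standardized \linkS4class{ProteinExperiment}.
#' @param assignment named protein -> module vector from
#'   \code{\link{detectModules}}.
#' @param power,minSize recorded network parameters (metadata only).
#' @return a \linkS4class{ModuleSet}.
#' @export
moduleEigengenes <- function(pe, assignment, power = 2, minSize = NULL) {
  X <- proteinValues(pe)
  if (!all(names(assignment) %in% colnames(X)))
    stop("assignment names must match matrix proteins")
  mods <- setdiff(unique(assignment), "grey")
  if (!length(mods)) stop("assignment defines no non-grey module")
  eg <- vapply(mods, function(m) {
    mem <- names(assignment)[assignment == m]
    .moduleEigengene(X[, mem, drop = FALSE])
  }, numeric(nrow(X)))
  rownames(eg) <- rownames(X)
  kme <- stats::cor(X[, names(assignment), drop = FALSE], eg)
  hubs <- vapply(mods, function(m) {
    mem <- sort(names(assignment)[assignment == m])
    mem[which.max(abs(kme[mem, m]))]
  }, character(1))
  if (is.null(minSize))
    minSize <- min(table(assignment[assignment != "grey"]))
  new("ModuleSet", assignment = assignment, power = power,
      minSize = as.integer(minSize), eigengenes = eg, hubs = hubs, kme = kme)
}

#' Module-trait association table
#'
#' Regresses each module eigengene against each clinical trait: logistic
#' regression for disease status, ordinary linear models for continuous
#' traits; "severity" uses the composite severity score (cases only).
#'
#' @param moduleSet a \linkS4class{ModuleSet} with eigengenes.
#' @param md sample metadata data.frame (row order matching the eigengene
#'   rows, or keyed by sample_id).
#' @param traits traits to test (default status, updrs3, moca, severity).
#' @param covariates optional adjustment covariates.
#' @return data.frame(module, trait, beta, se, p, n).
#' @export
moduleTraitAssociation <- function(moduleSet, md,
                                   traits = c("status", "updrs3", "moca",
                                              "severity"),
                                   covariates = NULL) {
  eg <- moduleEigengeneMatrix(moduleSet)
  if (!ncol(eg)) stop("module eigengenes not computed")
  if ("severity" %in% traits) {
    sv <- severityScore(md)
    key <- if ("sample_id" %in% colnames(md)) md$sample_id else rownames(md)
    md$severity <- scores(sv)[match(key, names(scores(sv)))]
  }
  out <- do.call(rbind, lapply(colnames(eg), function(m) {
    do.call(rbind, lapply(traits, function(tr) {
      r <- signatureAssociation(stats::setNames(eg[, m], rownames(eg)),
                                md, outcome = tr, covariates = covariates)
      data.frame(module = m, trait = tr, beta = r$beta, se = r$se, p = r$p,
                 n = r$n, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
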
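#' Read a protein expression matrix from delimited text
#'
#' Expects tab-separated text with one header row and one identifier column.
#' Both export dialects are handled: samples in rows (default) or proteins in
#' rows; either way the result is normalized to a raw-RFU
#' \linkS4class{ProteinExperiment}.
#'
#' @param path path to a TSV file.
#' @param orientation "samples" if rows are samples (default), "proteins" if
#'   rows are protein assays.
#' @param transformState transform state of the stored values; defaults to
#'   "raw", in which case strictly positive values are enforced.
#' @return a \linkS4class{ProteinExperiment}.
#' @export
readExpressionMatrix <- function(path, orientation = c("samples", "proteins"),
                                 transformState = "raw") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus at least one value column")
  ids <- as.character(df[[1L]])
  hdr <- colnames(df)[-1L]
  if (anyDuplicated(hdr))
    stop("duplicate column id(s): ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   vals[[j]][bad[1L]], bad[1L], hdr[j]))
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "proteins") m <- t(m)
  ProteinExperiment(m, transformState = transformState)
}

#' Write a ProteinExperiment's values to tab-separated text
#'
#' Samples in rows, proteins in columns, full double precision, so that a
#' write-then-read round trip is the identity up to float formatting.
#'
#' @param pe a \linkS4class{ProteinExperiment}.
#' @param path output path.
#' @param idColumn name of the identifier column header.
#' @export
writeExpressionMatrix <- function(pe, path, idColumn = "sample_id") {
  m <- proteinValues(pe)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.STATUS_LEVELS <- c("control", "case")

#' Read and validate a sample metadata table
#'
#' Tab-separated text with named columns; a \code{status} column with labels
#' "case"/"control" is required. MoCA is validated to [0, 30], MDS-UPDRS III
#' to >= 0. Missing values (empty string or "NA") are preserved as NA, never
#' imputed.
#'
#' @param path path to a TSV file with a \code{sample_id} column.
#' @return a data.frame keyed by \code{sample_id}.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (!"sample_id" %in% colnames(df)) stop("missing sample_id column")
  if (!"status" %in% colnames(df)) stop("missing status column")
  validateSampleMetadata(df)
}

#' Validate a sample metadata data.frame
#'
#' @param df data.frame with at least sample_id and status columns.
#' @return the validated data.frame, with status as a factor
#'   (levels control, case).
#' @export
validateSampleMetadata <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  st <- as.character(df$status)
  bad <- setdiff(unique(st[!is.na(st)]), .STATUS_LEVELS)
  if (length(bad))
    stop("unknown status label(s): ", paste(bad, collapse = ", "))
  df$status <- factor(st, levels = .STATUS_LEVELS)
  if ("moca" %in% colnames(df)) {
    m <- df$moca
    if (any(!is.na(m) & (m < 0 | m > 30)))
      stop("moca outside [0, 30] for sample(s): ",
           paste(df$sample_id[!is.na(m) & (m < 0 | m > 30)], collapse = ", "))
  }
  if ("updrs3" %in% colnames(df)) {
    u <- df$updrs3
    if (any(!is.na(u) & u < 0))
      stop("updrs3 must be >= 0 for sample(s): ",
           paste(df$sample_id[!is.na(u) & u < 0], collapse = ", "))
  }
  df
}

#' Write a sample metadata table to tab-separated text
#' @param df metadata data.frame.
#' @param path output path.
#' @export
writeSampleMetadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Attach metadata to a ProteinExperiment, keeping the sample intersection
#'
#' Samples present in only one of the two inputs are dropped; the count of
#' dropped samples is recorded in \code{metadata(pe)$joinReport} and both
#' structures end up in identical sample order.
#'
#' @param pe a \linkS4class{ProteinExperiment}.
#' @param md a metadata data.frame with a \code{sample_id} column.
#' @return the ProteinExperiment restricted to shared samples, with
#'   \code{colData} filled in.
#' @export
joinSampleMetadata <- function(pe, md) {
  md <- validateSampleMetadata(md)
  keep <- intersect(sampleIds(pe), md$sample_id)
  if (!length(keep)) stop("no samples shared between matrix and metadata")
  droppedPe <- setdiff(sampleIds(pe), keep)
  droppedMd <- setdiff(md$sample_id, keep)
  out <- pe[, keep]
  rows <- md[match(keep, md$sample_id), , drop = FALSE]
  SummarizedExperiment::colData(out) <-
    S4Vectors::DataFrame(rows, row.names = keep)
  S4Vectors::metadata(out)$joinReport <-
    list(nDroppedMatrix = length(droppedPe), nDroppedMetadata = length(droppedMd))
  out
}

#' Read a gene-set collection in GMT format
#'
#' Each line is \code{name<TAB>description<TAB>member1<TAB>member2...}.
#' Members are de-duplicated per set; set names must be unique and every set
#' non-empty.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors, with per-set descriptions in
#'   \code{attr(, "description")}.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set collection: ", path)
  sets <- vector("list", length(lines))
  nm <- desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(f)))
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nm))
    stop("duplicate set name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}
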
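#' Load an ASV dataset from delimited files
#'
#' Reads an ASV count table (TSV matrix or BIOM), sample metadata, qPCR
#' totals and optionally taxonomy, cross-validates them and returns a
#' single \linkS4class{AsvExperiment}. The count TSV has ASVs as rows,
#' samples as columns and first column header \code{asv_id}; metadata
#' columns are \code{sample_id, maize, nematode, day, replicate,
#' shared_baseline} (0/1 flags); the qPCR table has \code{sample_id,
#' total_copies}; taxonomy has \code{asv_id} plus either one column per
#' rank or a single semicolon-delimited \code{lineage} column.
#'
#' @param countPath path to the count table.
#' @param metaPath path to the sample metadata TSV.
#' @param qpcrPath path to the qPCR totals TSV.
#' @param taxonomyPath optional path to the taxonomy TSV.
#' @param format \code{"tsv"} or \code{"biom"} (requires the
#'   \pkg{biomformat} package; both JSON and HDF5 dialects are accepted).
#' @return An \code{AsvExperiment}; the inferred \linkS4class{StudyDesign}
#'   is stored in \code{metadata(x)$design}.
#' @export
loadInputs <- function(countPath, metaPath, qpcrPath, taxonomyPath = NULL,
                       format = c("tsv", "biom")) {
  format <- match.arg(format)
  for (p in c(countPath, metaPath, qpcrPath, taxonomyPath))
    if (!file.exists(p)) rtStop("ParseError", "file not found: %s", p)
  counts <- if (format == "tsv") .readCountsTsv(countPath)
            else .readCountsBiom(countPath)
  meta <- .readTsv(metaPath)
  .requireCols(meta, c("sample_id", "maize", "nematode", "day",
                       "replicate", "shared_baseline"), "metadata")
  qpcr <- .readTsv(qpcrPath)
  .requireCols(qpcr, c("sample_id", "total_copies"), "qPCR")
  if (any(!is.finite(qpcr$total_copies)) || any(qpcr$total_copies <= 0))
    rtStop("ParseError", "qPCR totals must be strictly positive")
  totals <- stats::setNames(qpcr$total_copies, qpcr$sample_id)
  taxonomy <- if (!is.null(taxonomyPath)) .readTsv(taxonomyPath) else NULL
  x <- AsvExperiment(counts, meta, totals, taxonomy)
  ## incomplete designs (a day sampled in only part of the factorial) are
  ## schema errors; fixtures too small to carry a full design (one day or
  ## a single replicate) simply get no design attached
  design <- tryCatch(inferStudyDesign(sampleInfo(x)),
                     rtError = function(e) stop(e),
                     error = function(e) NULL)
  if (!is.null(design)) S4Vectors::metadata(x)$design <- design
  x
}

.readTsv <- function(path) {
  out <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) rtStop("ParseError", "cannot parse %s: %s",
                               path, conditionMessage(e)))
  out
}

.requireCols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    rtStop("SchemaError", "%s table lacks required column(s): %s",
           what, paste(miss, collapse = ", "))
  invisible(df)
}

.readCountsTsv <- function(path) {
  df <- .readTsv(path)
  if (colnames(df)[1L] != "asv_id")
    rtStop("SchemaError", "count table must have first column 'asv_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$asv_id
  if (!is.numeric(m)) rtStop("ParseError", "non-numeric counts in %s", path)
  m
}

.readCountsBiom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    rtStop("ParseError", "the biomformat package is required for format='biom'")
  b <- tryCatch(biomformat::read_biom(path),
                error = function(e) rtStop("ParseError",
                                           "cannot parse BIOM file %s: %s",
                                           path, conditionMessage(e)))
  as(biomformat::biom_data(b), "matrix")
}

#' Write an AsvExperiment back to its four input tables
#'
#' Writes \code{counts.tsv}, \code{metadata.tsv}, \code{qpcr.tsv} and
#' \code{taxonomy.tsv} (if taxonomy is present) into \code{outDir}, in the
#' dialect that \code{\link{loadInputs}} reads, with deterministic row and
#' column order so repeated writes are byte-identical.
#'
#' @param x an \code{AsvExperiment}.
#' @param outDir output directory (created if needed).
#' @param overwrite allow overwriting existing files.
#' @return invisibly, the written file paths.
#' @export
writeDataset <- function(x, outDir, overwrite = FALSE) {
  meta <- sampleInfo(x)
  tabs <- list(
    counts = data.frame(asv_id = rownames(x),
                        as.data.frame(SummarizedExperiment::assay(x, "counts")),
                        check.names = FALSE),
    metadata = data.frame(
      sample_id = meta$sample_id,
      maize = as.integer(meta$maize), nematode = as.integer(meta$nematode),
      day = meta$day, replicate = meta$replicate,
      shared_baseline = as.integer(meta$shared_baseline)),
    qpcr = data.frame(sample_id = colnames(x),
                      total_copies = unname(qpcrTotals(x)))
  )
  rd <- SummarizedExperiment::rowData(x)
  have <- intersect(TAX_RANKS, colnames(rd))
  if (length(have))
    tabs$taxonomy <- data.frame(asv_id = rownames(x),
                                as.data.frame(rd[, have, drop = FALSE]),
                                row.names = NULL)
  writeResults(tabs, outDir, overwrite = overwrite)
}

#' Write a named list of result tables as TSV
#'
#' Each element of \code{results} is written as \code{<name>.tsv} with a
#' header, tab separation, no quoting and no row names. Writing is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param results named list of data.frames (matrices are converted).
#' @param outDir output directory, created if necessary.
#' @param overwrite if \code{FALSE} (default), refuse to overwrite any
#'   existing target file (\code{ExistsError}).
#' @return invisibly, character vector of written paths.
#' @export
writeResults <- function(results, outDir, overwrite = FALSE) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    rtStop("ParseError", "cannot create output directory %s", outDir)
  paths <- file.path(outDir, paste0(names(results), ".tsv"))
  clash <- paths[file.exists(paths)]
  if (!overwrite && length(clash))
    rtStop("ExistsError", "output file(s) already exist: %s",
           paste(basename(clash), collapse = ", "))
  for (i in seq_along(results)) {
    df <- results[[i]]
    if (is.matrix(df))
      df <- data.frame(id = rownames(df), as.data.frame(df),
                       check.names = FALSE)
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(paths)
}
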
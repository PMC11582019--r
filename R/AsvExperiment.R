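#' Construct an AsvExperiment
#'
#' Bundles an ASV x sample read-count matrix with sample metadata, qPCR
#' totals and (optionally) taxonomy into a validated
#' \linkS4class{AsvExperiment}.
#'
#' @param counts integer matrix, ASVs as rows, samples as columns, with
#'   dimnames.
#' @param sampleData data.frame or DataFrame with one row per sample and
#'   columns \code{sample_id}, \code{maize}, \code{nematode}, \code{day},
#'   \code{replicate}, \code{shared_baseline}.
#' @param qpcrTotals named numeric, total 16S rRNA gene copies per g dry
#'   soil per sample; must cover every sample in \code{counts}.
#' @param taxonomy optional data.frame with column \code{asv_id} plus
#'   ranked-lineage columns (\code{domain} ... \code{genus}); a
#'   \code{display_family} column is derived (see
#'   \code{\link{displayFamily}}).
#' @return An \code{AsvExperiment}.
#' @examples
#' counts <- matrix(1:4, 2, 2, dimnames = list(c("asv1", "asv2"),
#'                                             c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), maize = c(0, 1),
#'                    nematode = 0, day = 0, replicate = 1:2,
#'                    shared_baseline = 1)
#' AsvExperiment(counts, meta, c(s1 = 2e8, s2 = 3e8))
#' @export
AsvExperiment <- function(counts, sampleData, qpcrTotals, taxonomy = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  sampleData <- as.data.frame(sampleData)
  req <- c("sample_id", "maize", "nematode", "day", "replicate",
           "shared_baseline")
  miss <- setdiff(req, colnames(sampleData))
  if (length(miss))
    rtStop("SchemaError", "metadata lacks required column(s): %s",
           paste(miss, collapse = ", "))
  if (anyDuplicated(sampleData$sample_id))
    rtStop("DuplicateIdError", "duplicate sample ids in metadata")
  if (anyDuplicated(rownames(counts)))
    rtStop("DuplicateIdError", "duplicate ASV ids in count table")
  if (anyDuplicated(colnames(counts)))
    rtStop("DuplicateIdError", "duplicate sample ids in count table")
  absent <- setdiff(colnames(counts), sampleData$sample_id)
  if (length(absent))
    rtStop("MissingMetadataError",
           "sample(s) in counts absent from metadata: %s",
           paste(absent, collapse = ", "))
  noq <- setdiff(colnames(counts), names(qpcrTotals))
  if (length(noq))
    rtStop("MissingMetadataError",
           "sample(s) in counts absent from qPCR table: %s",
           paste(noq, collapse = ", "))
  sampleData <- sampleData[match(colnames(counts), sampleData$sample_id), ,
                           drop = FALSE]
  cd <- S4Vectors::DataFrame(
    maize = as.logical(as.integer(sampleData$maize)),
    nematode = as.logical(as.integer(sampleData$nematode)),
    day = as.integer(sampleData$day),
    replicate = as.integer(sampleData$replicate),
    shared_baseline = as.logical(as.integer(sampleData$shared_baseline)),
    total_copies = as.numeric(qpcrTotals[colnames(counts)]),
    row.names = colnames(counts)
  )
  rd <- .taxonomyRowData(rownames(counts), taxonomy)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
  new("AsvExperiment", se)
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

.taxonomyRowData <- function(asvIds, taxonomy) {
  if (is.null(taxonomy)) {
    rd <- S4Vectors::DataFrame(row.names = asvIds)
    rd$display_family <- rep("Unclassified", length(asvIds))
    return(rd)
  }
  taxonomy <- as.data.frame(taxonomy)
  if (!"asv_id" %in% colnames(taxonomy))
    rtStop("SchemaError", "taxonomy table lacks column 'asv_id'")
  if ("lineage" %in% colnames(taxonomy) &&
      !all(TAX_RANKS %in% colnames(taxonomy))) {
    parts <- strsplit(as.character(taxonomy$lineage), ";", fixed = TRUE)
    for (i in seq_along(TAX_RANKS))
      taxonomy[[TAX_RANKS[i]]] <-
        trimws(vapply(parts, function(p)
          if (length(p) >= i) p[i] else "", character(1)))
  }
  have <- intersect(TAX_RANKS, colnames(taxonomy))
  idx <- match(asvIds, taxonomy$asv_id)
  rd <- S4Vectors::DataFrame(row.names = asvIds)
  for (r in have) {
    v <- as.character(taxonomy[[r]])[idx]
    v[is.na(v)] <- ""
    rd[[r]] <- v
  }
  rd$display_family <- displayFamily(rd)
  rd
}

#' Family-level display label with higher-rank fallback
#'
#' Returns the family name for each ASV; where the family is unnamed, the
#' next higher named rank is substituted with its rank appended in
#' parentheses (e.g. \code{"Vicinamibacterales (order)"}), so that
#' family-level roll-ups never lose ASVs to empty labels.
#'
#' @param taxonomy DataFrame/data.frame with (some of) the columns
#'   \code{domain}, \code{phylum}, \code{class}, \code{order},
#'   \code{family}.
#' @return character vector of non-empty display labels.
#' @export
displayFamily <- function(taxonomy) {
  n <- nrow(taxonomy)
  out <- rep("Unclassified", n)
  ladder <- c("family", "order", "class", "phylum", "domain")
  for (i in seq_len(n)) {
    for (r in ladder) {
      v <- if (r %in% colnames(taxonomy)) taxonomy[[r]][i] else ""
      if (!is.na(v) && nzchar(v)) {
        out[i] <- if (r == "family") v else sprintf("%s (%s)", v, r)
        break
      }
    }
  }
  out
}

## ---- accessors ------------------------------------------------------------

#' @rdname AsvExperiment
#' @param x an \code{AsvExperiment}.
#' @export
setGeneric("qpcrTotals", function(x) standardGeneric("qpcrTotals"))

#' @rdname AsvExperiment
#' @export
setMethod("qpcrTotals", "AsvExperiment", function(x) {
  v <- SummarizedExperiment::colData(x)$total_copies
  names(v) <- colnames(x)
  v
})

#' @rdname AsvExperiment
#' @export
setGeneric("studyDesign", function(x) standardGeneric("studyDesign"))

#' @rdname AsvExperiment
#' @export
setMethod("studyDesign", "AsvExperiment", function(x)
  inferStudyDesign(sampleInfo(x)))

#' Sample metadata as a plain data.frame
#' @param x an \code{AsvExperiment}.
#' @return data.frame with sample_id, maize, nematode, day, replicate,
#'   shared_baseline, total_copies.
#' @export
sampleInfo <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  data.frame(sample_id = colnames(x), cd, row.names = NULL)
}

#' Infer the factorial design from sample metadata
#'
#' Reconstructs the \linkS4class{StudyDesign} from per-sample records and
#' verifies its completeness: day 0 must be present, and every treatment
#' combination must be sampled at every post-baseline day. A day observed
#' in only part of the design (e.g. an extra day present for one arm only)
#' is a schema error.
#'
#' @param meta data.frame with columns maize, nematode, day, replicate,
#'   shared_baseline.
#' @return A \code{StudyDesign}.
#' @export
inferStudyDesign <- function(meta) {
  days <- sort(unique(as.integer(meta$day)))
  if (days[1L] != 0L)
    rtStop("SchemaError", "no day-0 samples in metadata")
  combos <- unique(meta[!meta$shared_baseline, c("maize", "nematode")])
  if (nrow(combos) == 0L) combos <- unique(meta[, c("maize", "nematode")])
  cellN <- integer(0)
  for (i in seq_len(nrow(combos))) {
    for (d in days) {
      ids <- cellSamples(meta, combos$maize[i], combos$nematode[i], d)
      if (length(ids) == 0L)
        rtStop("SchemaError",
               "day %d has no samples for treatment %s: incomplete design",
               d, treatmentLabel(combos$maize[i], combos$nematode[i]))
      cellN <- c(cellN, length(ids))
    }
  }
  StudyDesign(days = days, replicates = min(cellN),
              sharedBaseline = any(meta$shared_baseline))
}

## ---- treatment helpers ----------------------------------------------------

#' Treatment labels
#'
#' Treatments are labelled \code{"+A"/"-A"} for nematode
#' (\emph{A. buetschlii}) addition and \code{"+M"/"-M"} for maize litter,
#' joined as e.g. \code{"+A/-M"}. The canonical output order is
#' \code{-A/-M, -A/+M, +A/-M, +A/+M}.
#'
#' @param maize,nematode logical vectors.
#' @return character vector of labels.
#' @export
treatmentLabel <- function(maize, nematode) {
  paste0(ifelse(nematode, "+A", "-A"), "/", ifelse(maize, "+M", "-M"))
}

#' @rdname treatmentLabel
#' @export
canonicalTreatments <- function()
  c("-A/-M", "-A/+M", "+A/-M", "+A/+M")

#' @rdname treatmentLabel
#' @param label treatment label(s) as produced by \code{treatmentLabel}.
#' @return \code{treatmentFlags}: data.frame with logical columns
#'   \code{maize}, \code{nematode}.
#' @export
treatmentFlags <- function(label) {
  data.frame(maize = grepl("\\+M", label), nematode = grepl("\\+A", label))
}

#' Samples contributing to a (treatment, day) cell
#'
#' Day-0 baseline samples flagged \code{shared_baseline} were taken before
#' nematode addition and are shared between the two nematode arms of their
#' maize level: they are returned for either value of \code{nematode}.
#'
#' @param meta sample metadata data.frame (see \code{\link{sampleInfo}}).
#' @param maize,nematode logical flags selecting the treatment.
#' @param day integer day.
#' @return character vector of sample ids.
#' @export
cellSamples <- function(meta, maize, nematode, day) {
  sel <- meta$day == day & meta$maize == maize &
    (meta$nematode == nematode | (day == 0L & meta$shared_baseline))
  meta$sample_id[sel]
}
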
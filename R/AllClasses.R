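#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

RESPONSE_TYPES <- c("A", "B", "C", "D", "E")
TYPE_LEVELS <- c(RESPONSE_TYPES, "STABLE")

#' Factorial microcosm sampling design
#'
#' Describes the destructive-sampling design of a two-factor soil microcosm
#' experiment: presence/absence of maize litter crossed with presence/absence
#' of an added bacterivorous nematode population, sampled at a fixed series
#' of incubation days with a fixed number of replicates per cell. Day-0
#' samples may be shared between the two nematode arms of each maize level
#' (the nematode addition happens at day 0, so pre-addition baselines are
#' common to both arms).
#'
#' @slot days integer vector of incubation days, strictly increasing,
#'   starting at 0.
#' @slot replicates number of replicate microcosms sampled per cell.
#' @slot sharedBaseline logical; if \code{TRUE}, day-0 samples are shared
#'   between the +/- nematode arms of each maize level.
#'
#' @export
setClass("StudyDesign", representation(
  days = "integer",
  replicates = "integer",
  sharedBaseline = "logical"
))

setValidity("StudyDesign", function(object) {
  d <- object@days
  if (length(d) < 2L) return("need at least 2 days")
  if (d[1L] != 0L) return("first day must be 0")
  if (any(diff(d) <= 0L)) return("days must be strictly increasing")
  if (object@replicates < 2L) return("replicates must be >= 2")
  TRUE
})

#' @param days integer vector of incubation days (first must be 0).
#' @param replicates positive integer, replicate microcosms per cell.
#' @param sharedBaseline logical, whether day-0 samples are shared between
#'   nematode arms.
#' @return A \code{StudyDesign} object.
#' @examples
#' StudyDesign()  # the default 5-day, 3-replicate design
#' @rdname StudyDesign-class
#' @export
StudyDesign <- function(days = c(0L, 4L, 8L, 16L, 32L), replicates = 3L,
                        sharedBaseline = TRUE) {
  new("StudyDesign", days = as.integer(days),
      replicates = as.integer(replicates),
      sharedBaseline = isTRUE(sharedBaseline))
}

#' @export
setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign: 2 (maize) x 2 (nematode) factorial\n")
  cat("  days:       ", paste(object@days, collapse = ", "), "\n")
  cat("  replicates: ", object@replicates, "\n")
  cat("  shared day-0 baseline:", object@sharedBaseline, "\n")
})

#' ASV count experiment with qPCR scaling
#'
#' \code{AsvExperiment} is a \linkS4class{SummarizedExperiment} holding an
#' ASV x sample read-count matrix (assay \code{"counts"}), per-sample
#' treatment metadata (\code{colData} columns \code{maize}, \code{nematode},
#' \code{day}, \code{replicate}, \code{shared_baseline}) together with the
#' qPCR-measured total 16S rRNA gene copy number per gram dry soil
#' (\code{total_copies}), and per-ASV taxonomy in \code{rowData}. An
#' absolute-abundance assay (\code{"abundance"}, copies per g dry soil) is
#' added by \code{\link{toAbsolute}}.
#'
#' @export
setClass("AsvExperiment", contains = "SummarizedExperiment")

.REQ_COLDATA <- c("maize", "nematode", "day", "replicate",
                  "shared_baseline", "total_copies")

setValidity("AsvExperiment", function(object) {
  cn <- colnames(object)
  rn <- rownames(object)
  if (is.null(rn) || is.null(cn))
    return("ASV and sample ids are required as dimnames")
  if (anyDuplicated(rn)) return("duplicate ASV ids")
  if (anyDuplicated(cn)) return("duplicate sample ids")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnts <- SummarizedExperiment::assay(object, "counts")
  if (any(cnts < 0)) return("counts must be non-negative")
  if (any(cnts != round(cnts))) return("counts must be integral")
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.REQ_COLDATA, colnames(cd))
  if (length(miss))
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (any(!is.finite(cd$total_copies)) || any(cd$total_copies <= 0))
    return("total_copies must be strictly positive")
  if (any(cd$shared_baseline & cd$day != 0L))
    return("shared_baseline samples are only allowed at day 0")
  TRUE
})

#' Planted ground truth of a synthetic dataset
#'
#' Container for the response archetypes, effect sizes and baseline
#' abundances planted by \code{\link{simulateDataset}}, and (for
#' respiration simulations) the planted peak days. Used to score recovery
#' of response types by the analysis pipeline.
#'
#' @slot types \code{DataFrame} with columns \code{asv_id},
#'   \code{treatment}, \code{type}, \code{effect_size}.
#' @slot baselines named numeric, per-ASV baseline abundance
#'   (copies per g dry soil).
#' @slot peakDays named numeric, per-treatment planted respiration peak day
#'   (empty for count simulations).
#' @export
setClass("SimTruth", representation(
  types = "DataFrame",
  baselines = "numeric",
  peakDays = "numeric"
))

#' @export
setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@baselines), "ASVs,",
      nrow(object@types), "(ASV, treatment) planted types\n")
  if (nrow(object@types))
    print(table(object@types$type))
  if (length(object@peakDays)) {
    cat("planted respiration peak days:\n")
    print(object@peakDays)
  }
})

#' ASV selection report
#'
#' Result of the three-stage responsive-ASV selection cascade: Hill-number
#' (\eqn{^2D}) dominance in at least one sample, replicate prevalence in
#' every (treatment, day) cell, and Pareto selection on summed absolute
#' abundance ranges.
#'
#' @slot dominant character, ASVs dominant in at least one sample.
#' @slot prevalent character, ASVs passing the replicate prevalence filter.
#' @slot responsive character, final Pareto-selected responsive ASVs.
#' @slot scores named numeric, per-candidate responsiveness score (summed
#'   abundance range over treatments, copies per g dry soil).
#' @slot coverage achieved cumulative score fraction of the selection.
#' @slot fraction the requested Pareto fraction.
#' @export
setClass("SelectionReport", representation(
  dominant = "character",
  prevalent = "character",
  responsive = "character",
  scores = "numeric",
  coverage = "numeric",
  fraction = "numeric"
))

#' @export
setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport\n")
  cat("  dominant in >=1 sample:", length(object@dominant), "ASVs\n")
  cat("  prevalent:             ", length(object@prevalent), "ASVs\n")
  cat(sprintf("  responsive (Pareto %.0f%%): %d ASVs (coverage %.3f)\n",
              100 * object@fraction, length(object@responsive),
              object@coverage))
})

#' Per-(ASV, treatment) abundance trajectories
#'
#' Matrix-backed collection of replicate-mean abundance trajectories, one
#' row per (ASV, treatment) pair, one column per incubation day.
#'
#' @slot values numeric matrix, rows = (ASV, treatment) pairs, columns =
#'   days; replicate-mean absolute abundances (copies per g dry soil), or
#'   z-scores after \code{\link{scaleTrajectories}}.
#' @slot asv character, ASV id per row.
#' @slot treatment character, treatment label per row (e.g. \code{"+A/-M"}).
#' @slot days integer, the day grid (column order).
#' @export
setClass("TrajectorySet", representation(
  values = "matrix",
  asv = "character",
  treatment = "character",
  days = "integer"
))

setValidity("TrajectorySet", function(object) {
  if (nrow(object@values) != length(object@asv) ||
      nrow(object@values) != length(object@treatment))
    return("row annotation length mismatch")
  if (ncol(object@values) != length(object@days))
    return("column/day length mismatch")
  TRUE
})

#' @export
setMethod("show", "TrajectorySet", function(object) {
  cat("TrajectorySet:", nrow(object@values), "trajectories over days",
      paste(object@days, collapse = ", "), "\n")
  cat("  ASVs:", length(unique(object@asv)),
      " treatments:", paste(sort(unique(object@treatment)), collapse = " "),
      "\n")
})

#' @rdname TrajectorySet-class
#' @param x a \code{TrajectorySet}.
#' @export
trajectoryValues <- function(x) x@values

#' @rdname TrajectorySet-class
#' @export
trajectoryInfo <- function(x)
  S4Vectors::DataFrame(asv_id = x@asv, treatment = x@treatment)
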
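#' Transform read counts to absolute abundances
#'
#' Scales each sample's relative read proportions by its qPCR-measured
#' total 16S rRNA gene copy number, so that
#' \eqn{value(i,s) = count(i,s)/depth(s) \times total(s)} and every column
#' sums to its qPCR total. The result is stored as assay
#' \code{"abundance"} (copies per g dry soil).
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @return \code{x} with an added \code{"abundance"} assay.
#' @export
toAbsolute <- function(x) {
  counts <- SummarizedExperiment::assay(x, "counts")
  depth <- colSums(counts)
  if (any(depth == 0))
    rtStop("ZeroDepthError", "sample(s) with zero total reads: %s",
           paste(colnames(x)[depth == 0], collapse = ", "))
  abund <- sweep(counts, 2, qpcrTotals(x) / depth, `*`)
  SummarizedExperiment::assay(x, "abundance") <- abund
  x
}

#' @rdname toAbsolute
#' @return \code{absoluteAbundance}: the abundance matrix (computed on the
#'   fly if the assay is absent).
#' @export
absoluteAbundance <- function(x) {
  if (!"abundance" %in% SummarizedExperiment::assayNames(x))
    x <- toAbsolute(x)
  SummarizedExperiment::assay(x, "abundance")
}

#' Hill numbers of a community profile
#'
#' Effective numbers of taxa at diversity orders q = 0 (richness), 1
#' (exponential Shannon, "abundant" taxa) and 2 (inverse Simpson,
#' "dominant" taxa).
#'
#' @param p non-negative relative abundance vector summing to 1
#'   (tolerance 1e-9).
#' @param q diversity order, one of 0, 1, 2.
#' @return the effective number \eqn{^qD}.
#' @examples
#' hillNumber(c(0.8, 0.2), 2)  # 1/0.68
#' @export
hillNumber <- function(p, q) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    rtStop("NormalizationError",
           "p must be a non-negative vector summing to 1")
  p <- p[p > 0]
  switch(as.character(q),
         "0" = length(p),
         "1" = exp(-sum(p * log(p))),
         "2" = 1 / sum(p^2),
         rtStop("ConfigError", "q must be 0, 1 or 2"))
}

#' @rdname hillNumber
#' @return \code{hillNumbers}: named vector \code{c(d0, d1, d2)}.
#' @export
hillNumbers <- function(p)
  c(d0 = hillNumber(p, 0), d1 = hillNumber(p, 1), d2 = hillNumber(p, 2))

## round-half-up integerisation of the 2D dominance cutoff
.roundHalfUp <- function(x) floor(x + 0.5)

#' Select ASVs dominant in at least one sample
#'
#' For every sample, the number of dominant ASVs is the Hill number
#' \eqn{^2D} of its abundance profile, rounded half-up (minimum 1); that
#' sample's dominant set is its top-n most abundant ASVs (ties broken by
#' ASV id). The union over samples is returned.
#'
#' @param x an \code{AsvExperiment} (absolute abundances are computed if
#'   needed).
#' @return character vector of dominant ASV ids (in input row order).
#' @export
selectDominantAsvs <- function(x) {
  abund <- absoluteAbundance(x)
  if (ncol(abund) == 0 || nrow(abund) == 0)
    rtStop("ConfigError", "empty abundance table")
  dom <- logical(nrow(abund))
  ids <- rownames(abund)
  for (s in seq_len(ncol(abund))) {
    v <- abund[, s]
    p <- v / sum(v)
    n <- max(1L, .roundHalfUp(hillNumber(p, 2)))
    ord <- order(-v, ids)
    dom[ord[seq_len(min(n, length(v)))]] <- TRUE
  }
  ids[dom]
}

#' Replicate prevalence filter
#'
#' Keeps an ASV only if it is detected (at least one read) in at least
#' \code{minDetected} replicates of \emph{every} (treatment, day) cell of
#' the design (\code{mode = "all"}), or of at least one cell
#' (\code{mode = "any"}). Day-0 shared-baseline samples count for both
#' nematode arms of their maize level. With \code{minDetected = NULL} the
#' threshold scales as \eqn{\lceil 2n/3 \rceil} with the cell's replicate
#' number n (2 of 3 in the default design).
#'
#' @param x an \code{AsvExperiment}.
#' @param minDetected integer detection threshold per cell, or \code{NULL}
#'   to scale with cell size.
#' @param mode \code{"all"} (strict; default) or \code{"any"}.
#' @return character vector of retained ASV ids.
#' @export
prevalenceFilter <- function(x, minDetected = 2L, mode = c("all", "any")) {
  mode <- match.arg(mode)
  counts <- SummarizedExperiment::assay(x, "counts")
  meta <- sampleInfo(x)
  design <- inferStudyDesign(meta)
  combos <- unique(meta[!meta$shared_baseline, c("maize", "nematode")])
  if (nrow(combos) == 0L) combos <- unique(meta[, c("maize", "nematode")])
  hits <- NULL
  for (i in seq_len(nrow(combos))) {
    for (d in design@days) {
      ids <- cellSamples(meta, combos$maize[i], combos$nematode[i], d)
      if (length(ids) == 0L)
        rtStop("DesignError", "empty (treatment, day) cell at day %d", d)
      thr <- if (is.null(minDetected)) ceiling(2 * length(ids) / 3)
             else minDetected
      if (length(ids) < thr)
        rtStop("DesignError",
               "cell at day %d has %d sample(s) but threshold is %d",
               d, length(ids), thr)
      det <- rowSums(counts[, ids, drop = FALSE] > 0) >= thr
      hits <- if (is.null(hits)) {
        if (mode == "all") det else det
      } else if (mode == "all") hits & det else hits | det
    }
  }
  rownames(counts)[hits]
}

## per-(ASV, treatment) responsiveness score: range (max - min over days)
## of the replicate-mean trajectory, summed over treatments
.responsivenessScores <- function(x, candidates) {
  traj <- buildTrajectories(x, candidates)
  v <- trajectoryValues(traj)
  rng <- apply(v, 1, function(r) max(r) - min(r))
  rowsum(rng, traj@asv)[candidates, 1]
}

#' Pareto selection of responsive ASVs
#'
#' Scores each candidate ASV by its summed absolute abundance range: per
#' treatment, the replicate-mean trajectory's max minus min over days,
#' summed over the treatments. Candidates are ranked by score (descending,
#' ties by ASV id) and the shortest prefix whose cumulative score reaches
#' \code{fraction} of the total is selected.
#'
#' @param x an \code{AsvExperiment}.
#' @param candidates character vector of candidate ASV ids.
#' @param fraction target cumulative score fraction in (0, 1].
#' @param dominant,prevalent optional upstream sets recorded in the
#'   report.
#' @return a \linkS4class{SelectionReport}.
#' @export
paretoResponsive <- function(x, candidates, fraction = 0.8,
                             dominant = character(0),
                             prevalent = character(0)) {
  if (length(candidates) == 0)
    rtStop("ConfigError", "no candidate ASVs")
  if (fraction <= 0 || fraction > 1)
    rtStop("ConfigError", "fraction must be in (0, 1]")
  scores <- .responsivenessScores(x, candidates)
  ord <- order(-scores, names(scores))
  cum <- cumsum(scores[ord])
  total <- cum[length(cum)]
  nSel <- if (total == 0) length(scores) else
    which(cum >= fraction * total - 1e-12)[1L]
  sel <- names(scores)[ord][seq_len(nSel)]
  new("SelectionReport",
      dominant = dominant, prevalent = prevalent,
      responsive = sel, scores = scores[ord],
      coverage = if (total == 0) 1 else unname(cum[nSel] / total),
      fraction = fraction)
}

#' Three-stage responsive-ASV selection cascade
#'
#' Runs the dominance, prevalence and Pareto filters in sequence:
#' responsive ASVs are Pareto-selected among those that are dominant in at
#' least one sample \emph{and} pass the replicate prevalence rule.
#'
#' @inheritParams paretoResponsive
#' @inheritParams prevalenceFilter
#' @return a \linkS4class{SelectionReport}.
#' @export
selectResponsiveAsvs <- function(x, fraction = 0.8, minDetected = 2L,
                                 mode = "all") {
  dominant <- selectDominantAsvs(x)
  prevalent <- prevalenceFilter(x, minDetected = minDetected, mode = mode)
  candidates <- intersect(dominant, prevalent)
  if (length(candidates) == 0)
    rtStop("ConfigError",
           "no ASVs are both dominant and prevalent; nothing to select")
  paretoResponsive(x, candidates, fraction = fraction,
                   dominant = dominant, prevalent = prevalent)
}

#' @rdname SelectionReport-class
#' @param report a \code{SelectionReport}.
#' @export
responsiveAsvs <- function(report) report@responsive

#' @rdname SelectionReport-class
#' @export
selectionScores <- function(report) report@scores

#' @rdname SelectionReport-class
#' @export
selectionAsDataFrame <- function(report) {
  sc <- report@scores
  data.frame(asv_id = names(sc), score = unname(sc),
             cum_fraction = cumsum(sc) / sum(sc),
             dominant = names(sc) %in% report@dominant,
             prevalent = names(sc) %in% report@prevalent,
             responsive = names(sc) %in% report@responsive)
}
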
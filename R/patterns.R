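#' Assemble cross-treatment response-type patterns
#'
#' Collects each ASV's response types over the four treatment combinations
#' into an ordered pattern tuple (canonical order
#' \code{-A/-M, -A/+M, +A/-M, +A/+M}) and attaches the ASV's median and
#' mean absolute abundance over every sample of the dataset.
#'
#' @param assignments assignment table from
#'   \code{\link{assignResponseTypes}}.
#' @param x the \linkS4class{AsvExperiment} the assignments came from.
#' @return data.frame with columns \code{asv_id}, one type column per
#'   treatment, \code{pattern} (comma-joined tuple),
#'   \code{median_abundance}, \code{mean_abundance}.
#' @export
assemblePatterns <- function(assignments, x) {
  a <- as.data.frame(assignments)
  treatments <- canonicalTreatments()
  asvs <- unique(a$asv_id)
  wide <- matrix(NA_character_, length(asvs), 4,
                 dimnames = list(asvs, treatments))
  for (i in seq_len(nrow(a)))
    wide[a$asv_id[i], a$treatment[i]] <- a$response_type[i]
  if (anyNA(wide)) {
    bad <- asvs[apply(is.na(wide), 1, any)]
    rtStop("IncompleteAssignmentError",
           "ASV(s) lacking assignments in some treatment: %s",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  abund <- absoluteAbundance(x)[asvs, , drop = FALSE]
  data.frame(asv_id = asvs,
             stats::setNames(as.data.frame(wide), treatments),
             pattern = apply(wide, 1, paste, collapse = ","),
             median_abundance = apply(abund, 1, stats::median),
             mean_abundance = rowMeans(abund),
             row.names = NULL, check.names = FALSE)
}

#' Rank response-type patterns by summed median abundance
#'
#' Groups ASVs sharing an identical pattern tuple, scores each group by
#' the sum of its members' median abundances, sorts the groups descending
#' (ties broken by lexicographic tuple order) and selects the shortest
#' prefix whose cumulative score reaches \code{coverage} of the total.
#'
#' @param patterns pattern table from \code{\link{assemblePatterns}}.
#' @param coverage target cumulative score fraction in (0, 1].
#' @return list with \code{table} (per-pattern data.frame: pattern,
#'   n_asvs, score, cum_fraction, selected) and \code{coverage} achieved
#'   by the selection.
#' @export
rankPatterns <- function(patterns, coverage = 0.8) {
  if (coverage <= 0 || coverage > 1)
    rtStop("ConfigError", "coverage must be in (0, 1]")
  score <- rowsum(patterns$median_abundance, patterns$pattern)
  n <- as.vector(table(patterns$pattern)[rownames(score)])
  ord <- order(-score[, 1], rownames(score))
  tab <- data.frame(pattern = rownames(score)[ord],
                    n_asvs = n[ord], score = score[ord, 1])
  cum <- cumsum(tab$score)
  total <- cum[length(cum)]
  nSel <- if (total == 0) nrow(tab) else
    which(cum >= coverage * total - 1e-12)[1L]
  tab$cum_fraction <- cum / total
  tab$selected <- seq_len(nrow(tab)) <= nSel
  list(table = tab, coverage = if (total == 0) 1 else cum[nSel] / total)
}

#' Succession-group assignment
#'
#' Classifies each ASV by when top-down control (grazing) overtakes
#' bottom-up control (litter) under the combined treatment. An ASV is
#' \emph{eligible} (grazing-susceptible) when it declines within the first
#' 8 days under grazing alone (type A or B in \code{+A/-M}) but not in
#' either no-nematode arm (\code{-A/+M} and \code{-A/-M} both not A/B).
#' Eligible ASVs are split by their combined-treatment (\code{+A/+M})
#' type: group I for type A (no benefit from litter), group II for type D
#' (turning point at day 4) and group III for type E (turning point
#' extended to day 8); any other combined-treatment type maps to
#' \code{NONE}.
#'
#' @param patterns pattern table from \code{\link{assemblePatterns}}.
#' @return data.frame with columns \code{asv_id}, \code{eligible},
#'   \code{group} (\code{"I"}, \code{"II"}, \code{"III"} or
#'   \code{"NONE"}).
#' @export
successionGroups <- function(patterns) {
  decline <- c("A", "B")
  elig <- patterns[["+A/-M"]] %in% decline &
    !(patterns[["-A/+M"]] %in% decline) &
    !(patterns[["-A/-M"]] %in% decline)
  grp <- rep("NONE", nrow(patterns))
  comb <- patterns[["+A/+M"]]
  grp[elig & comb == "A"] <- "I"
  grp[elig & comb == "D"] <- "II"
  grp[elig & comb == "E"] <- "III"
  data.frame(asv_id = patterns$asv_id, eligible = elig, group = grp)
}

#' Taxon-level roll-up of response types
#'
#' Sums the per-ASV median abundances (over all samples) within
#' (display family, response type, treatment) groups. ASVs without a
#' named family carry their next higher named rank as display label (see
#' \code{\link{displayFamily}}), so the roll-up conserves the ASV-level
#' total.
#'
#' @param assignments assignment table from
#'   \code{\link{assignResponseTypes}}.
#' @param x the \linkS4class{AsvExperiment}.
#' @return data.frame with columns \code{display_family},
#'   \code{treatment}, \code{response_type},
#'   \code{summed_median_abundance}, \code{n_asvs}.
#' @export
rollupByTaxon <- function(assignments, x) {
  a <- as.data.frame(assignments)
  fam <- SummarizedExperiment::rowData(x)$display_family
  names(fam) <- rownames(x)
  abund <- absoluteAbundance(x)
  med <- apply(abund[unique(a$asv_id), , drop = FALSE], 1, stats::median)
  a$display_family <- fam[a$asv_id]
  a$median_abundance <- med[a$asv_id]
  agg <- stats::aggregate(
    median_abundance ~ display_family + treatment + response_type,
    data = a, FUN = sum)
  cnt <- stats::aggregate(
    median_abundance ~ display_family + treatment + response_type,
    data = a, FUN = length)
  agg$n_asvs <- cnt$median_abundance
  names(agg)[names(agg) == "median_abundance"] <- "summed_median_abundance"
  agg[order(agg$treatment, agg$response_type,
            -agg$summed_median_abundance), , drop = FALSE]
}

#' Response-type contribution to community abundance over time
#'
#' For every (treatment, day), sums the replicate-mean absolute abundances
#' of the assigned ASVs within each response type (STABLE forms its own
#' stratum), yielding the time-resolved contribution of each type to the
#' selected community's total abundance.
#'
#' @inheritParams rollupByTaxon
#' @return data.frame with columns \code{treatment}, \code{day},
#'   \code{response_type}, \code{abundance}.
#' @export
typeContribution <- function(assignments, x) {
  a <- as.data.frame(assignments)
  traj <- buildTrajectories(x, unique(a$asv_id))
  v <- trajectoryValues(traj)
  key <- paste(traj@asv, traj@treatment)
  type <- stats::setNames(a$response_type, paste(a$asv_id, a$treatment))[key]
  out <- list()
  for (tr in unique(traj@treatment)) {
    for (k in seq_along(traj@days)) {
      sel <- traj@treatment == tr
      s <- rowsum(v[sel, k], type[sel])
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, day = traj@days[k],
        response_type = rownames(s), abundance = s[, 1], row.names = NULL)
    }
  }
  do.call(rbind, out)
}
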
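## Fixture builders shared across test files. Everything is generated in
## code; no data files are read.

suppressMessages(library(SummarizedExperiment))

## metadata for a full factorial design (optionally with shared day-0
## baselines generated once per maize level)
makeDesignMeta <- function(days = c(0, 4, 8, 16, 32), reps = 3,
                           shared = TRUE,
                           nematodeLevels = c(FALSE, TRUE)) {
  rows <- list()
  for (mz in c(FALSE, TRUE)) {
    if (shared) {
      rows[[length(rows) + 1L]] <- data.frame(
        maize = mz, nematode = FALSE, day = 0L, replicate = seq_len(reps),
        shared_baseline = 1L)
    } else {
      for (nem in nematodeLevels)
        rows[[length(rows) + 1L]] <- data.frame(
          maize = mz, nematode = nem, day = 0L, replicate = seq_len(reps),
          shared_baseline = 0L)
    }
    for (nem in nematodeLevels)
      for (d in days[-1L])
        rows[[length(rows) + 1L]] <- data.frame(
          maize = mz, nematode = nem, day = d, replicate = seq_len(reps),
          shared_baseline = 0L)
  }
  meta <- do.call(rbind, rows)
  meta$sample_id <- sprintf("s%03d", seq_len(nrow(meta)))
  meta$maize <- as.integer(meta$maize)
  meta$nematode <- as.integer(meta$nematode)
  meta
}

## experiment whose absolute abundances equal the supplied count matrix
## (qPCR total per sample is set to its read depth)
makeIdentityExperiment <- function(counts, meta, taxonomy = NULL) {
  totals <- stats::setNames(colSums(counts), colnames(counts))
  AsvExperiment(counts, meta, totals, taxonomy)
}

## counts for a full design from a function value(asv, maize, nematode,
## day, replicate) -> non-negative integer
countsFromRule <- function(asvIds, meta, value) {
  m <- matrix(0, length(asvIds), nrow(meta),
              dimnames = list(asvIds, meta$sample_id))
  for (i in seq_along(asvIds))
    for (s in seq_len(nrow(meta)))
      m[i, s] <- value(asvIds[i], meta$maize[s] == 1,
                       meta$nematode[s] == 1, meta$day[s],
                       meta$replicate[s])
  m
}

## a tiny deterministic 3-ASV experiment over the full 54-sample design
tinyExperiment <- function() {
  meta <- makeDesignMeta()
  counts <- countsFromRule(c("asvA", "asvB", "asvC"), meta,
    function(a, mz, nem, d, r) {
      base <- switch(a, asvA = 100, asvB = 60, asvC = 40)
      base + switch(a, asvA = 2 * d, asvB = -d, asvC = 0) + r
    })
  makeIdentityExperiment(counts, meta)
}

## assignment DataFrame for hand-built pattern tests
makeAssignments <- function(asvs, types) {
  ## types: list per asv of length-4 vector in canonical treatment order
  tr <- canonicalTreatments()
  do.call(rbind, lapply(seq_along(asvs), function(i)
    S4Vectors::DataFrame(asv_id = asvs[i], treatment = tr,
                         response_type = types[[i]],
                         cluster_id = NA_integer_,
                         template_correlation = NA_real_)))
}
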
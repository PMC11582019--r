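## Independent brute-force oracles used by both the module tests and the
## acceptance suite. Deliberately written as direct transcriptions of the
## selection and grouping rules, not via the package's own code paths.

oracleDominant <- function(abund) {
  ids <- rownames(abund)
  keep <- character(0)
  for (s in seq_len(ncol(abund))) {
    p <- abund[, s] / sum(abund[, s])
    n <- max(1, floor(1 / sum(p^2) + 0.5))
    keep <- union(keep, ids[order(-abund[, s], ids)][seq_len(n)])
  }
  keep
}

oraclePrevalence <- function(counts, meta, minDetected = 2) {
  combos <- unique(meta[meta$shared_baseline == 0, c("maize", "nematode")])
  ok <- rep(TRUE, nrow(counts))
  for (i in seq_len(nrow(combos))) {
    for (d in sort(unique(meta$day))) {
      ids <- meta$sample_id[meta$day == d & meta$maize == combos$maize[i] &
                              (meta$nematode == combos$nematode[i] |
                                 (d == 0 & meta$shared_baseline == 1))]
      ok <- ok & rowSums(counts[, ids, drop = FALSE] > 0) >= minDetected
    }
  }
  rownames(counts)[ok]
}

oraclePareto <- function(scores, fraction) {
  ord <- order(-scores, names(scores))
  total <- sum(scores)
  for (n in seq_along(scores)) {
    if (sum(scores[ord][seq_len(n)]) >= fraction * total - 1e-12)
      return(sort(names(scores)[ord][seq_len(n)]))
  }
}

## responsiveness scores recomputed from first principles
oracleScores <- function(x) {
  abund <- absoluteAbundance(x)
  meta <- sampleInfo(x)
  days <- sort(unique(meta$day))
  combos <- unique(meta[meta$shared_baseline == 0, c("maize", "nematode")])
  sc <- setNames(numeric(nrow(abund)), rownames(abund))
  for (a in rownames(abund)) {
    for (i in seq_len(nrow(combos))) {
      tr <- vapply(days, function(d) {
        ids <- meta$sample_id[meta$day == d & meta$maize == combos$maize[i] &
                                (meta$nematode == combos$nematode[i] |
                                   (d == 0 & meta$shared_baseline == 1))]
        mean(abund[a, ids])
      }, numeric(1))
      sc[a] <- sc[a] + max(tr) - min(tr)
    }
  }
  sc
}

## succession rule, tuple in canonical order (-A/-M, -A/+M, +A/-M, +A/+M)
oracleSuccession <- function(tuple) {
  declinesGrazed <- tuple[3] %in% c("A", "B")
  declinesUngrazed <- tuple[1] %in% c("A", "B") || tuple[2] %in% c("A", "B")
  if (!declinesGrazed || declinesUngrazed) return("NONE")
  switch(tuple[4], A = "I", D = "II", E = "III", "NONE")
}
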
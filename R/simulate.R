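## Synthetic datasets with planted ground truth.
##
## The generator emulates the factorial microcosm study: 2 (maize) x 2
## (nematode) treatments, destructive sampling at days 0/4/8/16/32 with 3
## replicates, day-0 samples shared between nematode arms of a maize level
## (54 samples in the default design), community totals around 2.35e8 16S
## copies per g dry soil, and multinomial read sampling. Per (ASV,
## treatment), one of six response archetypes is planted on the log
## abundance scale.

#' Response archetype templates
#'
#' Unit-amplitude temporal shapes \eqn{g(t)} of the five canonical response
#' types, evaluated on the design's day grid (\eqn{\max|g| = 1}):
#' \describe{
#'   \item{A}{steady decline, \eqn{g(t) = -t/\max(days)}.}
#'   \item{B}{intermediate minimum at day 8 with recovery,
#'     \eqn{g(t) = -\exp(-((t-8)/w_B)^2)}.}
#'   \item{C}{steady increase, \eqn{g(t) = +t/\max(days)}.}
#'   \item{D}{intermediate peak at day 4,
#'     \eqn{g(t) = \exp(-((t-4)/w_D)^2)}.}
#'   \item{E}{intermediate peak at day 8,
#'     \eqn{g(t) = \exp(-((t-8)/w_E)^2)}.}
#'   \item{STABLE}{no response, \eqn{g(t) = 0}.}
#' }
#'
#' @param type one of \code{"A","B","C","D","E","STABLE"}.
#' @param days integer day grid including 0.
#' @param peak optional peak (or minimum) day override for B/D/E.
#' @param width optional Gaussian width override (days); defaults
#'   \eqn{w_D = 6}, \eqn{w_E = w_B = 8}.
#' @return numeric vector \eqn{g(t)} over \code{days}.
#' @examples
#' archetypeTemplate("D", c(0, 4, 8, 16, 32))
#' @export
archetypeTemplate <- function(type, days = c(0, 4, 8, 16, 32),
                              peak = NULL, width = NULL) {
  if (!0 %in% days) rtStop("ConfigError", "day grid must include day 0")
  switch(type,
    A = -days / max(days),
    C = days / max(days),
    D = {
      p <- if (is.null(peak)) 4 else peak
      w <- if (is.null(width)) 6 else width
      exp(-((days - p) / w)^2)
    },
    E = {
      p <- if (is.null(peak)) 8 else peak
      w <- if (is.null(width)) 8 else width
      exp(-((days - p) / w)^2)
    },
    B = {
      p <- if (is.null(peak)) 8 else peak
      w <- if (is.null(width)) 8 else width
      -exp(-((days - p) / w)^2)
    },
    STABLE = rep(0, length(days)),
    rtStop("UnknownTypeError", "unknown response type '%s'", type)
  )
}

#' @rdname archetypeTemplate
#' @return \code{archetypeTemplates}: matrix of all five typed templates
#'   (rows A..E) over \code{days}.
#' @export
archetypeTemplates <- function(days = c(0, 4, 8, 16, 32)) {
  m <- t(vapply(RESPONSE_TYPES, archetypeTemplate, numeric(length(days)),
                days = days))
  colnames(m) <- as.character(days)
  m
}

#' Simulation configuration
#'
#' Collects all knobs of the count-table generator. Defaults encode the
#' emulated study conditions; \code{preset = "recovery"} is the compact
#' preset used for planted-type recovery experiments (200 ASVs, read depth
#' 1e4).
#'
#' @param sAsvs number of ASVs.
#' @param depth multinomial read depth per sample.
#' @param design a \linkS4class{StudyDesign}.
#' @param totalCopies expected community total, 16S copies per g dry soil.
#' @param baselineSdLog lognormal sd (log scale) of per-ASV baseline
#'   abundances, controlling rank-abundance skew.
#' @param sigmaRep replicate noise sd on the log abundance scale.
#' @param cvQpcr lognormal noise sd (log scale) on qPCR totals.
#' @param overdispersion Dirichlet-multinomial precision; \code{NULL} for
#'   pure multinomial sampling.
#' @param mixture named probabilities over types A..E and STABLE for the
#'   per-ASV base archetype.
#' @param effectSize log-scale amplitude of planted responses.
#' @param switchProb probability that a treatment re-draws its type from
#'   the mixture instead of inheriting the ASV's base type (creates
#'   non-trivial cross-treatment response patterns).
#' @param widths named Gaussian widths for templates D, E, B (days).
#' @param preset \code{NULL} or \code{"recovery"}.
#' @return a list of class \code{"rtSimConfig"}.
#' @export
simConfig <- function(sAsvs = 1000, depth = 1e5, design = StudyDesign(),
                      totalCopies = 2.35e8, baselineSdLog = 1.5,
                      sigmaRep = 0.2, cvQpcr = 0.2, overdispersion = NULL,
                      mixture = c(A = 0.15, B = 0.15, C = 0.15,
                                  D = 0.20, E = 0.20, STABLE = 0.15),
                      effectSize = 1.5, switchProb = 0.3,
                      widths = c(D = 6, E = 8, B = 8),
                      preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "recovery")
    sAsvs <- 200
    depth <- 1e4
  }
  if (is.null(names(mixture)) || !setequal(names(mixture), TYPE_LEVELS))
    rtStop("ConfigError", "mixture must be named over %s",
           paste(TYPE_LEVELS, collapse = ","))
  mixture <- mixture[TYPE_LEVELS]
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8)
    rtStop("ConfigError", "mixture weights must be >= 0 and sum to 1")
  if (sAsvs < 2) rtStop("ConfigError", "need at least 2 ASVs")
  if (depth < 100) rtStop("ConfigError", "depth must be >= 100")
  structure(list(sAsvs = sAsvs, depth = depth, design = design,
                 totalCopies = totalCopies, baselineSdLog = baselineSdLog,
                 sigmaRep = sigmaRep, cvQpcr = cvQpcr,
                 overdispersion = overdispersion, mixture = mixture,
                 effectSize = effectSize, switchProb = switchProb,
                 widths = widths),
            class = "rtSimConfig")
}

## sample table of the factorial design; day-0 rows are generated once per
## maize level and flagged shared_baseline when the design shares them.
.designSamples <- function(design) {
  days <- design@days
  reps <- seq_len(design@replicates)
  rows <- list()
  for (mz in c(FALSE, TRUE)) {
    if (design@sharedBaseline) {
      rows[[length(rows) + 1L]] <- data.frame(
        maize = mz, nematode = FALSE, day = 0L, replicate = reps,
        shared_baseline = TRUE)
    } else {
      for (nem in c(FALSE, TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          maize = mz, nematode = nem, day = 0L, replicate = reps,
          shared_baseline = FALSE)
    }
    for (nem in c(FALSE, TRUE))
      for (d in days[-1L])
        rows[[length(rows) + 1L]] <- data.frame(
          maize = mz, nematode = nem, day = d, replicate = reps,
          shared_baseline = FALSE)
  }
  meta <- do.call(rbind, rows)
  arm <- ifelse(meta$shared_baseline, "sh",
                ifelse(meta$nematode, "pA", "mA"))
  meta$sample_id <- sprintf("%s_%s_d%02d_r%d",
                            ifelse(meta$maize, "pM", "mM"),
                            arm, meta$day, meta$replicate)
  meta[, c("sample_id", "maize", "nematode", "day", "replicate",
           "shared_baseline")]
}

.PROMINENT_FAMILIES <- data.frame(
  family = c("Nitrososphaeraceae", "Chitinophagaceae", "Gemmatimonadaceae",
             "Sphingomonadaceae", "Xanthomonadaceae", "Comamonadaceae",
             "Blastocatellaceae", "Pyrinomonadaceae", "Nitrosomonadaceae",
             "Nitrospiraceae", "Micrococcaceae", "Bacillaceae"),
  phylum = c("Nitrososphaerota", "Bacteroidota", "Gemmatimonadota",
             "Pseudomonadota", "Pseudomonadota", "Pseudomonadota",
             "Acidobacteriota", "Acidobacteriota", "Pseudomonadota",
             "Nitrospirota", "Actinobacteriota", "Bacillota"),
  domain = c("Archaea", rep("Bacteria", 11)),
  stringsAsFactors = FALSE
)

.simulateTaxonomy <- function(asvIds) {
  n <- length(asvIds)
  pick <- sample.int(nrow(.PROMINENT_FAMILIES), n, replace = TRUE)
  tax <- data.frame(asv_id = asvIds,
                    domain = .PROMINENT_FAMILIES$domain[pick],
                    phylum = .PROMINENT_FAMILIES$phylum[pick],
                    class = "", order = "",
                    family = .PROMINENT_FAMILIES$family[pick],
                    genus = "", stringsAsFactors = FALSE)
  ## a slice of ASVs without a validly named family exercises the
  ## display-label fallback to the next higher rank
  unnamed <- sample.int(n, max(1L, round(0.1 * n)))
  tax$family[unnamed] <- ""
  tax$order[unnamed] <- "Vicinamibacterales"
  tax
}

#' Simulate a complete ASV dataset with planted ground truth
#'
#' Draws per-ASV baseline abundances from a lognormal rank-abundance
#' distribution scaled to the configured community total, plants one
#' response archetype per (ASV, treatment), and generates for every sample
#' of the design: true abundances
#' \eqn{x = \exp(\log b_i + e \cdot g_{type}(t) + N(0, \sigma_{rep}^2))},
#' read counts via multinomial (optionally Dirichlet-multinomial) sampling
#' of the true proportions at the configured depth, and a qPCR total equal
#' to the true column total under lognormal measurement noise. Shared
#' day-0 samples are generated once per maize level; where an ASV's
#' planted types differ between the two nematode arms, the baseline sample
#' uses the mean of the two arms' day-0 log effects (the arms are
#' indistinguishable before nematode addition).
#'
#' @param config an \code{\link{simConfig}} object.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with elements \code{experiment}
#'   (\linkS4class{AsvExperiment}) and \code{truth}
#'   (\linkS4class{SimTruth}).
#' @export
simulateDataset <- function(config = simConfig(), seed = 1) {
  stopifnot(inherits(config, "rtSimConfig"))
  set.seed(seed)
  S <- config$sAsvs
  asvIds <- sprintf("asv%04d", seq_len(S))
  design <- config$design
  days <- design@days
  meta <- .designSamples(design)

  w <- stats::rlnorm(S, meanlog = 0, sdlog = config$baselineSdLog)
  baselines <- stats::setNames(w / sum(w) * config$totalCopies, asvIds)

  ## planted archetypes: per-ASV base type, re-drawn per treatment with
  ## probability switchProb
  treatments <- canonicalTreatments()
  baseType <- sample(TYPE_LEVELS, S, replace = TRUE, prob = config$mixture)
  typeMat <- matrix(baseType, S, 4, dimnames = list(asvIds, treatments))
  for (j in seq_along(treatments)) {
    flip <- stats::runif(S) < config$switchProb
    if (any(flip))
      typeMat[flip, j] <- sample(TYPE_LEVELS, sum(flip), replace = TRUE,
                                 prob = config$mixture)
  }

  ## template value per (type, day)
  tmpl <- rbind(archetypeTemplates(days), STABLE = rep(0, length(days)))
  for (tp in c("D", "E", "B"))
    tmpl[tp, ] <- archetypeTemplate(tp, days, width = config$widths[[tp]])
  e <- config$effectSize

  counts <- matrix(0, S, nrow(meta), dimnames = list(asvIds, meta$sample_id))
  totals <- numeric(nrow(meta))
  dayIdx <- match(meta$day, days)
  for (s in seq_len(nrow(meta))) {
    if (meta$shared_baseline[s]) {
      mzLab <- treatmentLabel(meta$maize[s], c(FALSE, TRUE))
      g <- (tmpl[typeMat[, mzLab[1]], dayIdx[s]] +
            tmpl[typeMat[, mzLab[2]], dayIdx[s]]) / 2
    } else {
      lab <- treatmentLabel(meta$maize[s], meta$nematode[s])
      g <- tmpl[typeMat[, lab], dayIdx[s]]
    }
    x <- exp(log(baselines) + e * g +
             stats::rnorm(S, 0, config$sigmaRep))
    totals[s] <- sum(x)
    p <- x / totals[s]
    if (!is.null(config$overdispersion)) {
      a <- stats::rgamma(S, shape = p * config$overdispersion, rate = 1)
      if (sum(a) == 0) a <- p
      p <- a / sum(a)
    }
    counts[, s] <- stats::rmultinom(1L, config$depth, p)
  }
  qpcr <- totals * exp(stats::rnorm(nrow(meta), 0, config$cvQpcr))
  names(qpcr) <- meta$sample_id
  tax <- .simulateTaxonomy(asvIds)

  x <- AsvExperiment(counts, meta, qpcr, tax)
  S4Vectors::metadata(x)$design <- design
  truth <- new("SimTruth",
               types = S4Vectors::DataFrame(
                 asv_id = rep(asvIds, times = 4),
                 treatment = rep(treatments, each = S),
                 type = as.vector(typeMat),
                 effect_size = ifelse(as.vector(typeMat) == "STABLE", 0, e)),
               baselines = baselines,
               peakDays = numeric(0))
  list(experiment = x, truth = truth)
}

#' @rdname SimTruth-class
#' @param truth a \code{SimTruth}.
#' @export
simTruthTypes <- function(truth) truth@types

#' @rdname SimTruth-class
#' @export
simTruthBaselines <- function(truth) truth@baselines

#' @rdname SimTruth-class
#' @export
simTruthPeakDays <- function(truth) truth@peakDays

## ---- respiration simulation ----------------------------------------------

#' Respiration simulation configuration
#'
#' True respiration rate curves are Gaussian bumps
#' \eqn{r(t) = base + amp \cdot \exp(-((t-peak)/\sigma)^2)} in
#' \eqn{\mu g\, CO_2\, (g\ soil\ DW)^{-1} h^{-1}}. Defaults plant the
#' treatment contrasts the pipeline is meant to detect: nematode addition
#' shifts the peak from day 12 to day 6, maize litter raises the
#' amplitude.
#'
#' @param peakDays named numeric, planted peak day per treatment label.
#' @param amplitudes named numeric, bump amplitude per treatment.
#' @param base baseline rate.
#' @param sigma bump width (days).
#' @param intervalDays titration interval length (days); traps are
#'   exchanged on this grid over days 0..32.
#' @param maxDay end of the incubation (days).
#' @param replicates microcosms per treatment.
#' @param soilDw g dry soil per microcosm.
#' @param hclBlank mL 0.1 M HCl consumed by blank titrations.
#' @param noiseCv multiplicative (lognormal) noise on the titrant volume
#'   consumed by trapped CO2.
#' @return list of class \code{"rtRespConfig"}.
#' @export
respConfig <- function(peakDays = c("-A/-M" = 12, "-A/+M" = 12,
                                    "+A/-M" = 6, "+A/+M" = 6),
                       amplitudes = c("-A/-M" = 0.6, "-A/+M" = 1.2,
                                      "+A/-M" = 0.6, "+A/+M" = 1.2),
                       base = 0.2, sigma = 5, intervalDays = 2, maxDay = 32,
                       replicates = 3, soilDw = 50, hclBlank = 5,
                       noiseCv = 0.1) {
  if (any(amplitudes <= 0))
    rtStop("ConfigError", "amplitudes must be positive")
  structure(list(peakDays = peakDays, amplitudes = amplitudes, base = base,
                 sigma = sigma, intervalDays = intervalDays, maxDay = maxDay,
                 replicates = replicates, soilDw = soilDw,
                 hclBlank = hclBlank, noiseCv = noiseCv),
            class = "rtRespConfig")
}

#' Simulate alkali-trap titration records
#'
#' Integrates the true rate curve over each trap interval to get the CO2
#' mass captured per microcosm, then back-computes the titration: the
#' volume of 0.1 M HCl consumed by the sample is the blank volume minus
#' \eqn{mass_{mg} / 2.2} (2.2 mg CO2 per mL of 0.1 M HCl), so that
#' \code{\link{co2Rate}} applied to a noiseless record recovers the
#' interval-mean rate exactly. Noise is multiplicative on the consumed
#' titrant difference.
#'
#' @param config a \code{\link{respConfig}}.
#' @param seed integer seed.
#' @return list with \code{titrations} (data.frame of titration records),
#'   \code{rateCurve} (function(treatment, t) of true rates) and
#'   \code{truth} (\linkS4class{SimTruth} carrying planted peak days).
#' @export
simulateRespiration <- function(config = respConfig(), seed = 1) {
  stopifnot(inherits(config, "rtRespConfig"))
  set.seed(seed)
  starts <- seq(0, config$maxDay - config$intervalDays,
                by = config$intervalDays)
  rate <- function(treatment, t)
    config$base + config$amplitudes[[treatment]] *
      exp(-((t - config$peakDays[[treatment]]) / config$sigma)^2)
  rows <- list()
  for (tr in names(config$peakDays)) {
    fl <- treatmentFlags(tr)
    for (rep in seq_len(config$replicates)) {
      id <- sprintf("mc_%s_r%d", gsub("[+/]", "", gsub("-", "o", tr)), rep)
      for (st in starts) {
        en <- st + config$intervalDays
        ## micrograms CO2 trapped in the interval: integral of the rate
        ## (per g per hour) over the interval (hours) times soil mass
        mass <- stats::integrate(function(t) rate(tr, t), st, en,
                                 rel.tol = 1e-10)$value * 24 * config$soilDw
        dHcl <- (mass / 1000) / 2.2
        if (config$noiseCv > 0)
          dHcl <- dHcl * exp(stats::rnorm(1, 0, config$noiseCv))
        rows[[length(rows) + 1L]] <- data.frame(
          microcosm_id = id, maize = fl$maize, nematode = fl$nematode,
          interval_start = st, interval_end = en,
          hcl_blank_ml = config$hclBlank,
          hcl_sample_ml = config$hclBlank - dHcl,
          soil_dw_g = config$soilDw)
      }
    }
  }
  titr <- do.call(rbind, rows)
  rownames(titr) <- NULL
  truth <- new("SimTruth", types = S4Vectors::DataFrame(),
               baselines = numeric(0), peakDays = config$peakDays)
  list(titrations = titr, rateCurve = rate, truth = truth)
}
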
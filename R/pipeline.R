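## End-to-end orchestration: simulate (or load) -> filter -> classify ->
## patterns -> composition (-> respiration), with a YAML run manifest.

## deterministic per-stage seeds derived from the single run seed, so a
## stage rerun in isolation reproduces its in-pipeline output
.stageSeed <- function(seed, stage) {
  offs <- c(simulate = 1L, respiration = 2L, classify = 3L, kselect = 4L)
  (as.integer(seed) * 101L + offs[[stage]]) %% .Machine$integer.max
}

#' Default pipeline configuration
#'
#' Returns the configuration list understood by \code{\link{runPipeline}}.
#' With \code{simulate = TRUE} the pipeline generates its inputs with
#' \code{\link{simulateDataset}} / \code{\link{simulateRespiration}};
#' otherwise \code{paths} must name the input files for
#' \code{\link{loadInputs}}.
#'
#' @param simulate logical; generate synthetic inputs.
#' @param sim a \code{\link{simConfig}} (used when \code{simulate}).
#' @param resp a \code{\link{respConfig}} or \code{NULL} to skip the
#'   respiration stage.
#' @param paretoFraction,minDetected selection-cascade parameters.
#' @param k,nstart,nFinal,theta response-typing parameters.
#' @param coverage pattern-ranking coverage.
#' @param priorStrength zero-replacement prior.
#' @param kSelection logical; run the cluster-number diagnostics (adds a
#'   \code{k_selection} output; the gap statistic makes this the slowest
#'   stage).
#' @param paths named list of input paths (counts, meta, qpcr, taxonomy)
#'   when \code{simulate = FALSE}.
#' @return configuration list.
#' @export
pipelineConfig <- function(simulate = TRUE,
                           sim = simConfig(preset = "recovery"),
                           resp = respConfig(),
                           paretoFraction = 0.8, minDetected = 2L,
                           k = 9, nstart = 25, nFinal = 5, theta = 0.25,
                           coverage = 0.8, priorStrength = 0.5,
                           kSelection = FALSE, paths = NULL) {
  list(simulate = simulate, sim = sim, resp = resp,
       paretoFraction = paretoFraction, minDetected = minDetected,
       k = k, nstart = nstart, nFinal = nFinal, theta = theta,
       coverage = coverage, priorStrength = priorStrength,
       kSelection = kSelection, paths = paths)
}

#' Run the full analysis pipeline
#'
#' Executes selection, response typing, pattern/succession analysis,
#' compositional beta diversity and (optionally) respiration on either a
#' simulated or a loaded dataset, writes every result table as TSV plus a
#' YAML run manifest, and returns the result bundle. Identical
#' configuration and seed produce byte-identical result tables.
#'
#' @param config configuration list from \code{\link{pipelineConfig}}, or
#'   the path of a YAML file holding one.
#' @param outDir output directory.
#' @param seed integer run seed; per-stage seeds are derived from it.
#' @param overwrite allow overwriting existing outputs.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results (experiment,
#'   truth, selection, assignments, patterns, ranking, succession,
#'   rollup, contribution, composition, respiration, manifest).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, seed = 42,
                        overwrite = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- .configFromYaml(config)
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, t) {
    timings[[stage]] <<- round(as.numeric(Sys.time()) - as.numeric(t), 3)
  }

  ## inputs
  t <- Sys.time()
  if (isTRUE(config$simulate)) {
    say("simulating dataset")
    sim <- simulateDataset(config$sim, seed = .stageSeed(seed, "simulate"))
    x <- sim$experiment
    truth <- sim$truth
  } else {
    say("loading inputs")
    p <- config$paths
    x <- loadInputs(p$counts, p$meta, p$qpcr, p$taxonomy)
    truth <- NULL
  }
  tick("inputs", t)

  ## selection cascade
  t <- Sys.time(); say("selecting responsive ASVs")
  selection <- selectResponsiveAsvs(x, fraction = config$paretoFraction,
                                    minDetected = config$minDetected)
  tick("filter", t)

  ## response typing
  t <- Sys.time(); say("classifying response types")
  assignments <- assignResponseTypes(
    x, selection, k = config$k, nstart = config$nstart,
    nFinal = config$nFinal, theta = config$theta,
    seed = .stageSeed(seed, "classify"))
  kReport <- NULL
  if (isTRUE(config$kSelection)) {
    traj <- buildTrajectories(x, responsiveAsvs(selection))
    v <- trajectoryValues(traj)
    keep <- !screenStability(v, theta = config$theta)
    sc <- t(apply(v[keep, , drop = FALSE], 1, scaleTrajectory))
    kReport <- suggestK(sc, seed = .stageSeed(seed, "kselect"))
  }
  tick("classify", t)

  ## patterns and succession
  t <- Sys.time(); say("assembling response patterns")
  patterns <- assemblePatterns(assignments, x)
  ranking <- rankPatterns(patterns, coverage = config$coverage)
  succession <- successionGroups(patterns)
  rollup <- rollupByTaxon(assignments, x)
  contribution <- typeContribution(assignments, x)
  tick("patterns", t)

  ## compositional beta diversity
  t <- Sys.time(); say("compositional analysis")
  comp <- compositionAnalysis(x, priorStrength = config$priorStrength)
  tick("compose", t)

  ## respiration
  respiration <- NULL
  if (!is.null(config$resp)) {
    t <- Sys.time(); say("respiration")
    rsim <- simulateRespiration(config$resp,
                                seed = .stageSeed(seed, "respiration"))
    respiration <- respirationSummary(rsim$titrations)
    respiration$titrations <- rsim$titrations
    respiration$truth <- rsim$truth
    tick("respire", t)
  }

  ## write outputs
  results <- list(
    selection_report = selectionAsDataFrame(selection),
    assignments = as.data.frame(assignments),
    patterns = patterns,
    pattern_ranking = ranking$table,
    succession = succession,
    rollup_family = rollup,
    type_contribution = contribution,
    pca_scores = data.frame(sample_id = rownames(comp$pca$scores),
                            comp$pca$scores[, seq_len(min(5,
                              ncol(comp$pca$scores))), drop = FALSE],
                            row.names = NULL),
    pca_explained = data.frame(component = seq_along(comp$pca$explained),
                               fraction = comp$pca$explained),
    varpart = data.frame(component = c(names(comp$varpart$fractions),
                                       "total", "residual"),
                         adj_r2 = c(unname(comp$varpart$fractions),
                                    comp$varpart$total,
                                    comp$varpart$residual))
  )
  if (!is.null(kReport))
    results$k_selection <- data.frame(
      method = c("wss", "silhouette", "gap"),
      suggested_k = c(kReport$wss$k, kReport$silhouette$k, kReport$gap$k))
  if (!is.null(respiration)) {
    results$respiration_rates <- respiration$rates
    results$respiration_peaks <- respiration$peaks
  }
  paths <- writeResults(results, outDir, overwrite = overwrite)
  dsPaths <- writeDataset(x, file.path(outDir, "dataset"),
                          overwrite = overwrite)

  manifest <- list(
    package = "resptyper",
    version = as.character(utils::packageVersion("resptyper")),
    seed = seed,
    config = .configForManifest(config),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(c(paths, dsPaths))),
      basename(c(paths, dsPaths)))),
    timings_s = timings,
    total_s = round(as.numeric(Sys.time()) - as.numeric(t0), 3)
  )
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  say("done")
  invisible(list(experiment = x, truth = truth, selection = selection,
                 assignments = assignments, patterns = patterns,
                 ranking = ranking, succession = succession,
                 rollup = rollup, contribution = contribution,
                 composition = comp, kReport = kReport,
                 respiration = respiration, manifest = manifest))
}

.configForManifest <- function(config) {
  cf <- config
  cf$sim <- if (!is.null(cf$sim)) unclass(cf$sim) else NULL
  if (!is.null(cf$sim)) {
    cf$sim$design <- list(days = cf$sim$design@days,
                          replicates = cf$sim$design@replicates,
                          sharedBaseline = cf$sim$design@sharedBaseline)
    cf$sim$mixture <- as.list(cf$sim$mixture)
    cf$sim$widths <- as.list(cf$sim$widths)
  }
  if (!is.null(cf$resp)) {
    cf$resp <- unclass(cf$resp)
    cf$resp$peakDays <- as.list(cf$resp$peakDays)
    cf$resp$amplitudes <- as.list(cf$resp$amplitudes)
  }
  cf
}

.configFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipelineConfig()
  for (nm in intersect(names(y), c("simulate", "paretoFraction",
                                   "minDetected", "k", "nstart", "nFinal",
                                   "theta", "coverage", "priorStrength",
                                   "kSelection")))
    cfg[[nm]] <- y[[nm]]
  if (!is.null(y$paths)) {
    cfg$paths <- y$paths
    cfg$simulate <- FALSE
  }
  if (!is.null(y$sim)) {
    s <- y$sim
    design <- if (!is.null(s$design))
      StudyDesign(s$design$days, s$design$replicates,
                  isTRUE(s$design$sharedBaseline)) else StudyDesign()
    args <- s[intersect(names(s), names(formals(simConfig)))]
    args$design <- design
    if (!is.null(args$mixture)) args$mixture <- unlist(args$mixture)
    cfg$sim <- do.call(simConfig, args)
  }
  if (!is.null(y$resp)) {
    r <- y$resp
    args <- r[intersect(names(r), names(formals(respConfig)))]
    if (!is.null(args$peakDays)) args$peakDays <- unlist(args$peakDays)
    if (!is.null(args$amplitudes)) args$amplitudes <- unlist(args$amplitudes)
    cfg$resp <- do.call(respConfig, args)
  } else if (isTRUE(y$noRespiration)) {
    cfg$resp <- NULL
  }
  cfg
}
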
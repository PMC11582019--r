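#' Build per-(ASV, treatment) abundance trajectories
#'
#' For each selected ASV and each of the four treatment combinations,
#' computes the replicate-mean absolute abundance at every design day.
#' Day-0 values come from the shared baseline samples of the matching
#' maize level, so the +A and -A trajectories of one maize level start at
#' the same value.
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @param asvs character vector of ASV ids.
#' @return a \linkS4class{TrajectorySet} ordered ASV-major with treatments
#'   in canonical order.
#' @export
buildTrajectories <- function(x, asvs) {
  if (length(asvs) == 0) rtStop("ConfigError", "empty ASV selection")
  abund <- absoluteAbundance(x)[asvs, , drop = FALSE]
  meta <- sampleInfo(x)
  design <- inferStudyDesign(meta)
  days <- design@days
  treatments <- canonicalTreatments()
  fl <- treatmentFlags(treatments)
  vals <- matrix(NA_real_, length(asvs) * 4L, length(days),
                 dimnames = list(NULL, as.character(days)))
  asvCol <- character(nrow(vals)); trCol <- character(nrow(vals))
  r <- 0L
  for (i in seq_along(asvs)) {
    for (j in seq_len(4L)) {
      r <- r + 1L
      asvCol[r] <- asvs[i]; trCol[r] <- treatments[j]
      for (k in seq_along(days)) {
        ids <- cellSamples(meta, fl$maize[j], fl$nematode[j], days[k])
        if (length(ids) == 0L)
          rtStop("DesignError", "no samples for %s at day %d",
                 treatments[j], days[k])
        vals[r, k] <- mean(abund[i, ids])
      }
    }
  }
  new("TrajectorySet", values = vals, asv = asvCol, treatment = trCol,
      days = days)
}

#' Temporal stability screen
#'
#' A trajectory is flagged temporally stable when its range (max - min) is
#' below \code{theta} times its median value, or its standard deviation is
#' zero. Stable trajectories are excluded from clustering and reported as
#' type \code{STABLE}.
#'
#' @param values numeric vector (one trajectory) or matrix (one per row).
#' @param theta relative range threshold (default 0.25).
#' @return logical, \code{TRUE} for stable.
#' @export
screenStability <- function(values, theta = 0.25) {
  f <- function(v) {
    if (stats::sd(v) == 0) return(TRUE)
    (max(v) - min(v)) < theta * stats::median(v)
  }
  if (is.matrix(values)) apply(values, 1, f) else f(values)
}

#' z-score a trajectory
#'
#' Centres to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator).
#'
#' @param values numeric vector.
#' @return scaled vector.
#' @export
scaleTrajectory <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    rtStop("ConstantTrajectoryError",
           "cannot scale a constant trajectory")
  (values - mean(values)) / s
}

#' @rdname scaleTrajectory
#' @param traj a \linkS4class{TrajectorySet}.
#' @return \code{scaleTrajectories}: the \code{TrajectorySet} with each
#'   row z-scored.
#' @export
scaleTrajectories <- function(traj) {
  traj@values <- t(apply(traj@values, 1, scaleTrajectory))
  traj
}

## ---- cluster number diagnostics -------------------------------------------

#' Suggest the number of k-means clusters
#'
#' Computes three standard diagnostics on the scaled trajectory matrix:
#' total within-cluster sum of squares (elbow located at the maximum
#' second difference), mean silhouette width (argmax over k = 2..kmax),
#' and the Tibshirani gap statistic (uniform reference in the
#' PCA-aligned bounding box, B = \code{nboot} bootstraps, first-SE
#' decision rule).
#'
#' @param scaled numeric matrix of z-scored trajectories (rows) or a
#'   \linkS4class{TrajectorySet}.
#' @param kmax largest k examined.
#' @param nboot reference sets for the gap statistic.
#' @param nstart k-means restarts per k.
#' @param seed integer seed.
#' @return list with per-method elements \code{wss}, \code{silhouette},
#'   \code{gap}, each holding \code{k} (the suggestion) and \code{curve}.
#' @export
suggestK <- function(scaled, kmax = 12, nboot = 50, nstart = 25, seed = 42) {
  X <- if (is(scaled, "TrajectorySet")) trajectoryValues(scaled) else scaled
  if (nrow(X) < kmax + 1)
    rtStop("TooFewItemsError", "need more than kmax = %d trajectories", kmax)
  set.seed(seed)
  wss <- vapply(seq_len(kmax), function(k)
    stats::kmeans(X, k, nstart = nstart, iter.max = 50)$tot.withinss,
    numeric(1))
  d2 <- diff(diff(wss))                 # second difference, k = 2..kmax-1
  kWss <- if (length(d2)) which.max(d2) + 1L else 1L

  D <- stats::dist(X)
  sil <- vapply(2:kmax, function(k) {
    cl <- stats::kmeans(X, k, nstart = nstart, iter.max = 50)$cluster
    mean(cluster::silhouette(cl, D)[, "sil_width"])
  }, numeric(1))
  kSil <- (2:kmax)[which.max(sil)]

  gap <- cluster::clusGap(X, FUN = function(x, k)
    list(cluster = stats::kmeans(x, k, nstart = nstart,
                                 iter.max = 50)$cluster),
    K.max = kmax, B = nboot, spaceH0 = "scaledPCA", verbose = FALSE)
  kGap <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                         method = "Tibs2001SEmax")

  list(wss = list(k = kWss, curve = data.frame(k = seq_len(kmax),
                                               wss = wss)),
       silhouette = list(k = kSil, curve = data.frame(k = 2:kmax,
                                                      width = sil)),
       gap = list(k = kGap,
                  curve = data.frame(k = seq_len(kmax),
                                     gap = gap$Tab[, "gap"],
                                     se = gap$Tab[, "SE.sim"])))
}

#' k-means clustering of scaled trajectories
#'
#' Best-of-\code{nstart} k-means with squared Euclidean distance;
#' deterministic given the seed.
#'
#' @inheritParams suggestK
#' @param k number of clusters (default 9).
#' @return list with \code{cluster} (integer labels), \code{centers}
#'   (k x days centroid matrix) and \code{tot.withinss}.
#' @export
clusterTrajectories <- function(scaled, k = 9, nstart = 25, seed = 42) {
  X <- if (is(scaled, "TrajectorySet")) trajectoryValues(scaled) else scaled
  nDistinct <- nrow(unique(X))
  if (k > nDistinct)
    rtStop("KTooLargeError",
           "k = %d exceeds the %d distinct trajectories", k, nDistinct)
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100)
  list(cluster = km$cluster, centers = km$centers,
       tot.withinss = km$tot.withinss)
}

## ---- merge and label -------------------------------------------------------

.scaledTemplates <- function(days) {
  t(apply(archetypeTemplates(days), 1, scaleTrajectory))
}

#' Merge k-means centroids and label them with response types
#'
#' Maps the k initial k-means clusters onto at most \code{nFinal}
#' archetype-labelled response types. In the default \code{"template"}
#' mode every centroid is labelled with the z-scored archetype template
#' (A-E) it has the highest Pearson correlation with; clusters sharing a
#' template are thereby merged, so k clusters collapse to at most five
#' types. A centroid correlating below 0.5 with every template still
#' receives its nearest label, with a \code{LabelConflictWarning} (such
#' clusters typically collect residual-noise trajectories that escaped the
#' stability screen). The \code{"agglomerate"} mode instead cuts a
#' complete-linkage tree on \eqn{1 - Pearson} correlation between
#' centroids at exactly \code{nFinal} groups and labels each merged
#' (size-weighted mean) centroid greedily with a unique template; it
#' reproduces a fixed-size merge but is brittle when a noise cluster
#' claims one of the groups. A \code{manualMap} (named vector, cluster id
#' to type) overrides everything.
#'
#' @param centers k x days centroid matrix (column names = days).
#' @param days integer day grid.
#' @param nFinal number of merged response types (default 5).
#' @param manualMap optional named character vector mapping cluster ids to
#'   types.
#' @param sizes optional cluster sizes used to weight the merged
#'   centroids in \code{"agglomerate"} mode.
#' @param method \code{"template"} (default) or \code{"agglomerate"}.
#' @return character vector of length k: response type per input cluster.
#' @export
mergeAndLabel <- function(centers, days, nFinal = 5, manualMap = NULL,
                          sizes = NULL,
                          method = c("template", "agglomerate")) {
  method <- match.arg(method)
  k <- nrow(centers)
  if (!is.null(manualMap)) {
    if (length(manualMap) != k)
      rtStop("ConfigError", "manualMap must cover all %d clusters", k)
    out <- as.character(manualMap)[order(as.integer(names(manualMap)))]
    return(out)
  }
  if (nFinal > k)
    rtStop("ConfigError", "nFinal exceeds the number of centroids")
  tmpl <- .scaledTemplates(days)

  if (method == "template") {
    corMat <- stats::cor(t(centers), t(tmpl))   # k x 5
    labels <- character(k)
    for (i in seq_len(k)) {
      j <- which.max(corMat[i, ])
      if (corMat[i, j] < 0.5)
        rtWarn("LabelConflictWarning",
               "centroid %d correlates only %.2f with its best template (%s)",
               i, corMat[i, j], colnames(corMat)[j])
      labels[i] <- colnames(corMat)[j]
    }
    return(labels)
  }

  ## agglomerate: complete linkage on 1 - cor, cut at exactly nFinal
  if (is.null(sizes)) sizes <- rep(1, k)
  groups <- if (nFinal == k) seq_len(k) else {
    cc <- stats::cor(t(centers))
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "complete")
    stats::cutree(hc, k = nFinal)
  }
  merged <- matrix(0, nFinal, ncol(centers))
  for (g in seq_len(nFinal)) {
    idx <- which(groups == g)
    merged[g, ] <- colSums(centers[idx, , drop = FALSE] * sizes[idx]) /
      sum(sizes[idx])
  }
  corMat <- stats::cor(t(merged), t(tmpl))   # nFinal x 5
  labels <- character(nFinal)
  openRows <- seq_len(nFinal); openCols <- seq_len(ncol(corMat))
  while (length(openRows)) {
    sub <- corMat[openRows, openCols, drop = FALSE]
    best <- arrayInd(which.max(sub), dim(sub))
    if (sub[best] < 0.5)
      rtWarn("LabelConflictWarning",
             "merged centroid %d correlates only %.2f with its best template",
             openRows[best[1]], sub[best])
    labels[openRows[best[1]]] <- colnames(corMat)[openCols[best[2]]]
    openRows <- openRows[-best[1]]
    if (length(openCols) > 1L) openCols <- openCols[-best[2]]
  }
  labels[groups]
}

## ---- orchestration ---------------------------------------------------------

#' Classify selected ASV trajectories into response types
#'
#' End-to-end response typing: builds the per-(ASV, treatment)
#' trajectories, screens out temporally stable ones, z-scores the rest,
#' pools all treatments into one k-means clustering, merges the k
#' centroids down to \code{nFinal} template-labelled response types, and
#' returns one assignment row per (selected ASV, treatment).
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @param selection a \linkS4class{SelectionReport} or character vector of
#'   ASV ids.
#' @param k initial k-means cluster number (default 9).
#' @param nstart k-means restarts (default 25).
#' @param nFinal merged response type count (default 5).
#' @param theta stability screen threshold (default 0.25).
#' @param manualMap optional cluster-to-type override for
#'   \code{\link{mergeAndLabel}}.
#' @param mergeMethod merge/label mode passed to
#'   \code{\link{mergeAndLabel}}.
#' @param seed integer seed (default 42).
#' @return \code{DataFrame} with columns \code{asv_id}, \code{treatment},
#'   \code{response_type}, \code{cluster_id} (NA for STABLE),
#'   \code{template_correlation}.
#' @export
assignResponseTypes <- function(x, selection, k = 9, nstart = 25,
                                nFinal = 5, theta = 0.25,
                                manualMap = NULL,
                                mergeMethod = "template", seed = 42) {
  asvs <- if (is(selection, "SelectionReport")) responsiveAsvs(selection)
          else selection
  traj <- buildTrajectories(x, asvs)
  v <- trajectoryValues(traj)
  stable <- screenStability(v, theta = theta)
  type <- rep("STABLE", nrow(v))
  clusterId <- rep(NA_integer_, nrow(v))
  corr <- rep(NA_real_, nrow(v))
  if (any(!stable)) {
    sc <- t(apply(v[!stable, , drop = FALSE], 1, scaleTrajectory))
    kUse <- min(k, nrow(unique(sc)))
    km <- clusterTrajectories(sc, k = kUse, nstart = nstart, seed = seed)
    map <- mergeAndLabel(km$centers, traj@days,
                         nFinal = min(nFinal, kUse),
                         manualMap = manualMap, method = mergeMethod,
                         sizes = as.numeric(table(factor(km$cluster,
                                                   levels = seq_len(kUse)))))
    tmpl <- .scaledTemplates(traj@days)
    type[!stable] <- map[km$cluster]
    clusterId[!stable] <- km$cluster
    corr[!stable] <- vapply(seq_len(nrow(sc)), function(i)
      stats::cor(sc[i, ], tmpl[map[km$cluster[i]], ]), numeric(1))
  }
  S4Vectors::DataFrame(asv_id = traj@asv, treatment = traj@treatment,
                       response_type = type, cluster_id = clusterId,
                       template_correlation = corr)
}
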
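#' Bayesian-multiplicative zero replacement
#'
#' Replaces zero counts by their posterior-expected proportion under a
#' Dirichlet prior with strength \code{priorStrength} per part
#' (\eqn{p_j = s / (n + s \cdot S)} for a zero part in a sample of depth
#' n over S parts), and multiplicatively rescales the non-zero parts so
#' each sample's proportions still sum to 1. Ratios among observed parts
#' are preserved, and every output entry is strictly positive.
#'
#' @param counts ASV x sample count matrix, or an
#'   \linkS4class{AsvExperiment}.
#' @param priorStrength Dirichlet prior strength per part (default 0.5).
#' @return sample x ASV matrix of strictly positive proportions (samples
#'   as rows, the orientation used by the compositional analyses).
#' @export
replaceZeros <- function(counts, priorStrength = 0.5) {
  if (is(counts, "AsvExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  X <- t(as.matrix(counts))                       # samples x ASVs
  n <- rowSums(X)
  if (any(n == 0))
    rtStop("ZeroDepthError", "sample(s) with zero total reads")
  S <- ncol(X)
  s <- priorStrength
  out <- X / n
  for (i in seq_len(nrow(X))) {
    z <- X[i, ] == 0
    if (!any(z)) next
    repl <- s / (n[i] + s * S)
    out[i, z] <- repl
    out[i, !z] <- out[i, !z] * (1 - sum(z) * repl)
  }
  out
}

#' Centred log-ratio transform
#'
#' \eqn{clr(x)_j = \ln x_j - \frac{1}{S}\sum_k \ln x_k} per sample (row).
#' Rows of the result sum to zero; the transform is invariant to
#' per-sample rescaling of the input.
#'
#' @param props sample x ASV matrix of strictly positive values.
#' @return sample x ASV CLR matrix.
#' @examples
#' clrTransform(matrix(c(1, 2, 4), 1))
#' @export
clrTransform <- function(props) {
  props <- as.matrix(props)
  if (any(props <= 0))
    rtStop("NonPositiveError", "CLR requires strictly positive input")
  lg <- log(props)
  lg - rowMeans(lg)
}

#' Aitchison PCA ordination
#'
#' Principal component analysis of the CLR matrix by centred
#' singular-value decomposition; pairwise Euclidean distances between CLR
#' rows are the Aitchison distances, and the full-rank score matrix
#' reproduces them exactly.
#'
#' @param clr sample x ASV CLR matrix.
#' @return list with \code{scores}, \code{loadings}, \code{explained}
#'   (variance fractions summing to 1) and \code{dist} (Aitchison
#'   distance matrix, class \code{dist}).
#' @export
aitchisonPca <- function(clr) {
  clr <- as.matrix(clr)
  if (nrow(clr) < 3)
    rtStop("ConfigError", "need at least 3 samples for ordination")
  pr <- stats::prcomp(clr, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  list(scores = pr$x, loadings = pr$rotation,
       explained = ev / sum(ev), dist = stats::dist(clr))
}

#' Variance partitioning of CLR beta diversity
#'
#' Partitions the variance of the CLR matrix explained by maize litter
#' (M), nematode addition (A) and incubation day as an unordered factor
#' (D) into unique and shared adjusted-R2 fractions. The adjusted R2 of a
#' redundancy analysis (RDA) is computed for every non-empty factor
#' subset, and the seven Venn fractions follow by inclusion-exclusion, so
#' they sum exactly to the full-model adjusted R2. Small negative
#' adjusted fractions are possible and reported as-is.
#'
#' @param clr sample x ASV CLR matrix (rows named by sample id).
#' @param meta sample metadata data.frame (\code{\link{sampleInfo}}) with
#'   rows matching \code{clr}.
#' @return list with \code{fractions} (named: M, A, D unique; M+A, M+D,
#'   A+D pairwise shared; M+A+D three-way shared), \code{total} (full
#'   model adjusted R2), \code{residual}, and \code{subsets} (adjusted R2
#'   of each factor subset).
#' @export
variancePartition <- function(clr, meta) {
  clr <- as.matrix(clr)
  meta <- as.data.frame(meta)
  i <- match(rownames(clr), meta$sample_id)
  if (anyNA(i))
    rtStop("MissingMetadataError", "CLR rows without metadata")
  env <- data.frame(M = factor(meta$maize[i]),
                    A = factor(meta$nematode[i]),
                    D = factor(meta$day[i]))
  if (any(vapply(env, nlevels, 1L) < 2L))
    rtStop("SingularDesignError",
           "each of maize, nematode and day needs >= 2 levels")
  adj <- function(vars) {
    f <- stats::as.formula(paste("clr ~", paste(vars, collapse = " + ")))
    vegan::RsquareAdj(vegan::rda(f, data = env))$adj.r.squared
  }
  aM <- adj("M"); aA <- adj("A"); aD <- adj("D")
  aMA <- adj(c("M", "A")); aMD <- adj(c("M", "D")); aAD <- adj(c("A", "D"))
  aMAD <- adj(c("M", "A", "D"))
  uM <- aMAD - aAD
  uA <- aMAD - aMD
  uD <- aMAD - aMA
  sMA <- aMD + aAD - aMAD - aD          # shared by M and A only
  sMD <- aMA + aAD - aMAD - aA
  sAD <- aMA + aMD - aMAD - aM
  sMAD <- aMAD - uM - uA - uD - sMA - sMD - sAD
  fr <- c("M" = uM, "A" = uA, "D" = uD,
          "M+A" = sMA, "M+D" = sMD, "A+D" = sAD, "M+A+D" = sMAD)
  list(fractions = fr, total = aMAD, residual = 1 - aMAD,
       subsets = c(M = aM, A = aA, D = aD, MA = aMA, MD = aMD,
                   AD = aAD, MAD = aMAD))
}

#' Full compositional beta-diversity analysis
#'
#' Convenience wrapper chaining zero replacement, CLR transform, Aitchison
#' PCA and variance partitioning.
#'
#' @param x an \linkS4class{AsvExperiment}.
#' @param priorStrength zero-replacement prior strength.
#' @return list with \code{clr}, \code{pca}, \code{varpart}.
#' @export
compositionAnalysis <- function(x, priorStrength = 0.5) {
  props <- replaceZeros(x, priorStrength = priorStrength)
  clr <- clrTransform(props)
  list(clr = clr, pca = aitchisonPca(clr),
       varpart = variancePartition(clr, sampleInfo(x)))
}
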
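# Downstream chemometrics on the fused pixel x feature matrix: Pearson
# correlation mapping, (optionally uncentered) PCA, hierarchical spectrum
# ordering, K-means feature clustering and the joint double-clustering
# display. All stochastic steps take an explicit seed.

#' Feature-by-feature Pearson correlation map
#'
#' Computes the Pearson correlation coefficient between all feature pairs
#' across pixels (the synchronous correlation display). Zero-variance
#' features (e.g. baseline anchor points forced to zero) are flagged and
#' their rows/columns set to \code{NA} rather than propagating NaN.
#'
#' @param x numeric matrix (pixels x features) or a
#'   \linkS4class{FusedMatrix} (retained pixels are used).
#' @param descriptors optional feature descriptor data.frame; taken from the
#'   fused matrix when available.
#' @param snrThreshold SNR gate for fused input, default 150.
#' @return A \linkS4class{CorrelationMap}.
#' @export
correlationMap <- function(x, descriptors = NULL, snrThreshold = 150) {
  if (is(x, "FusedMatrix")) {
    if (is.null(descriptors)) descriptors <- x@descriptors
    x <- x@values[retainedPixels(x, snrThreshold), , drop = FALSE]
  }
  if (nrow(x) < 2) stop("correlation needs at least 2 pixels")
  sdv <- apply(x, 2, stats::sd)
  zero <- !is.finite(sdv) | sdv == 0
  r <- matrix(NA_real_, ncol(x), ncol(x))
  if (any(!zero)) {
    r[!zero, !zero] <- stats::cor(x[, !zero, drop = FALSE])
  }
  if (is.null(descriptors))
    descriptors <- data.frame(kind = rep("feature", ncol(x)),
                              wavenumber = NA_real_, isotope = NA_character_,
                              replicate = 0L)
  new("CorrelationMap", matrix = r, descriptors = descriptors,
      zeroVariance = zero)
}

#' Principal component analysis with optional uncentered decomposition
#'
#' Components come from the singular value decomposition of the (optionally
#' mean-centered) pixel x feature matrix. When \code{center = FALSE} the
#' mean direction is not removed and the first component represents the mean
#' of the data, reproducing the uncentered convention used for fused
#' spectra. Variance fractions are squared singular values over their total.
#' The sign of each component is fixed so that its largest-magnitude loading
#' is positive.
#'
#' @param x numeric matrix (pixels x features) or \linkS4class{FusedMatrix}
#'   (retained pixels are used).
#' @param center subtract feature means first? Default \code{TRUE}.
#' @param nPc number of components to keep (default: all).
#' @param snrThreshold SNR gate for fused input, default 150.
#' @return A \linkS4class{PcaModel}.
#' @export
pcaSpectra <- function(x, center = TRUE, nPc = NULL, snrThreshold = 150) {
  if (is(x, "FusedMatrix"))
    x <- x@values[retainedPixels(x, snrThreshold), , drop = FALSE]
  x <- as.matrix(x)
  mu <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2, mu)
  maxPc <- min(dim(x))
  if (is.null(nPc)) nPc <- maxPc
  nPc <- min(nPc, maxPc)
  sv <- svd(xc, nu = nPc, nv = nPc)
  tot <- sum(sv$d^2)
  keep <- seq_len(nPc)
  # rank-deficient tails are dropped silently by svd's zero singular values
  sgn <- vapply(keep, function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  load <- sweep(sv$v[, keep, drop = FALSE], 2, sgn, "*")
  scr <- sweep(sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], nPc), 2, sgn, "*")
  new("PcaModel", loadings = load, scores = scr,
      varianceFraction = sv$d[keep]^2 / tot, centered = center,
      center = mu)
}

#' Reconstruct the data matrix from a PCA model
#'
#' @param model a \linkS4class{PcaModel}.
#' @return scores \%*\% t(loadings) plus the center.
#' @export
pcaReconstruct <- function(model) {
  stopifnot(is(model, "PcaModel"))
  sweep(model@scores %*% t(model@loadings), 2, -model@center)
}

#' Hierarchical leaf order of pixel spectra
#'
#' Agglomerative clustering on the Euclidean distance between spectra; the
#' returned permutation is the dendrogram leaf order. Agglomeration is
#' deterministic, with distance ties broken toward the lowest original
#' index. Ward linkage (ward.D2, squared-distance updates on Euclidean
#' input) is the default, the common choice in FTIR histopathology;
#' single/complete/average are selectable.
#'
#' @param x numeric matrix, rows are spectra.
#' @param linkage "ward" (default), "single", "complete" or "average".
#' @return Integer permutation of row indices.
#' @export
hcaOrder <- function(x, linkage = c("ward", "single", "complete", "average")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  if (nrow(x) < 2) stop("need at least 2 spectra")
  stats::hclust(stats::dist(x), method = method)$order
}

#' K-means clustering of features on their across-pixel profiles
#'
#' Features (columns) are clustered by the Euclidean K-means objective over
#' their pixel profiles. The best of \code{restarts} seeded random
#' initializations (centers drawn from distinct feature profiles) by lowest
#' within-cluster sum of squares wins; ties go to the lowest restart index.
#' Labels are canonicalized by first occurrence, so identical (e.g.
#' quintupled) columns always share a label and a fixed seed gives an
#' identical assignment.
#'
#' @param x numeric matrix (pixels x features).
#' @param K number of clusters, default 4.
#' @param restarts number of random initializations, default 10.
#' @param seed integer seed.
#' @return Integer vector of cluster labels (1..K) per feature.
#' @export
kmeansFeatures <- function(x, K = 4, restarts = 10, seed = 1) {
  profiles <- t(as.matrix(x))            # features x pixels
  nf <- nrow(profiles)
  if (K > nf) stop("K exceeds the number of features")
  distinct <- !duplicated(profiles)
  if (sum(distinct) < K)
    stop("K exceeds the number of distinct feature profiles")
  best <- NULL
  .withSeed(seed, {
    for (r in seq_len(restarts)) {
      centers <- profiles[sample(which(distinct), K), , drop = FALSE]
      # a restart that empties a cluster is merely a poor initialization;
      # it still yields a valid (high-inertia) assignment and loses
      km <- suppressWarnings(stats::kmeans(profiles, centers = centers,
                                           iter.max = 100,
                                           algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12)
        best <- km
    }
  })
  lab <- best$cluster
  first <- unique(lab)
  as.integer(match(lab, first))
}

#' Double clustering of a fused matrix
#'
#' Pixels passing the SNR gate (default 500, the stricter display
#' convention) are re-standardized per feature (mean subtraction, SD
#' division), ordered by hierarchical clustering, and the features are
#' partitioned into K (default 4) K-means clusters; the heatmap view sorted
#' on both axes is returned together with the cluster-ordered mean feature
#' vector computed prior to standardization (the "sorted spectrum").
#'
#' @param fused a \linkS4class{FusedMatrix}.
#' @param K feature clusters, default 4.
#' @param snrThreshold pixel gate, default 500.
#' @param seed integer seed for the K-means restarts.
#' @param restarts K-means restarts, default 10.
#' @param linkage HCA linkage, default "ward".
#' @return A \linkS4class{DoubleClusterResult}.
#' @export
doubleCluster <- function(fused, K = 4, snrThreshold = 500, seed = 1,
                          restarts = 10, linkage = "ward") {
  stopifnot(is(fused, "FusedMatrix"))
  keep <- retainedPixels(fused, snrThreshold)
  if (sum(keep) < 2) stop("fewer than 2 pixels pass the SNR gate")
  raw <- fused@values[keep, , drop = FALSE]
  mu <- colMeans(raw)
  sdv <- apply(raw, 2, stats::sd)
  sdv[sdv == 0] <- 1                      # zero-variance features stay zero
  z <- sweep(sweep(raw, 2, mu), 2, sdv, "/")
  ord <- hcaOrder(z, linkage = linkage)
  assign <- kmeansFeatures(z, K = K, restarts = restarts, seed = seed)
  fOrd <- order(assign, seq_along(assign))
  new("DoubleClusterResult",
      spectrumOrder = as.integer(which(keep)[ord]),
      featureAssignment = assign,
      featureOrder = as.integer(fOrd),
      K = as.integer(K),
      sortedMatrix = z[ord, fOrd, drop = FALSE],
      sortedSpectrum = mu[fOrd],
      descriptors = fused@descriptors[fOrd, , drop = FALSE])
}

#' Cross-block correlation summary
#'
#' Summaries of absolute Pearson correlations between the FTIR and element
#' blocks (and within each block), quantifying the orthogonality of the two
#' modalities: independent modalities leave the cross-block maximum below
#' the multiple-testing null bound.
#'
#' @param corr a \linkS4class{CorrelationMap} whose descriptors distinguish
#'   "wavenumber" from "element" features.
#' @return List with \code{crossMax}, \code{crossMean}, \code{withinFtirMax},
#'   \code{withinFtirMean}, \code{withinElementMax}, \code{withinElementMean}
#'   and \code{nCrossPairs} (distinct pairs, replicates collapsed).
#' @export
crossBlockSummary <- function(corr) {
  stopifnot(is(corr, "CorrelationMap"))
  d <- corr@descriptors
  if (!all(c("wavenumber", "element") %in% d$kind))
    stop("descriptors do not distinguish the FTIR and element blocks")
  wn <- which(d$kind == "wavenumber" & !corr@zeroVariance)
  # collapse replicated element columns: keep replicate 1 of each isotope
  el <- which(d$kind == "element" & d$replicate <= 1 & !corr@zeroVariance)
  m <- corr@matrix
  cross <- abs(m[wn, el, drop = FALSE])
  offdiag <- function(idx) {
    sub <- abs(m[idx, idx, drop = FALSE])
    sub[upper.tri(sub)]
  }
  wnOff <- offdiag(wn)
  elOff <- offdiag(el)
  list(crossMax = max(cross), crossMean = mean(cross),
       withinFtirMax = if (length(wnOff)) max(wnOff) else NA_real_,
       withinFtirMean = if (length(wnOff)) mean(wnOff) else NA_real_,
       withinElementMax = if (length(elOff)) max(elOff) else NA_real_,
       withinElementMean = if (length(elOff)) mean(elOff) else NA_real_,
       nCrossPairs = length(cross))
}

#' Bonferroni-corrected null bound for a set of correlation coefficients
#'
#' Fisher-z bound: the magnitude below which the maximum of \code{nPairs}
#' null Pearson correlations at sample size \code{n} stays with family-wise
#' level \code{alpha}.
#'
#' @param n sample size (pixels).
#' @param nPairs number of tested pairs.
#' @param alpha family-wise error rate, default 0.05.
#' @return Critical |r|.
#' @export
correlationNullBound <- function(n, nPairs, alpha = 0.05) {
  stopifnot(n > 3, nPairs >= 1)
  tanh(stats::qnorm(1 - alpha / (2 * nPairs)) / sqrt(n - 3))
}
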
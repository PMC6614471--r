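# Correlation mapping, PCA, HCA, K-means and double clustering against
# brute-force, closed-form and separation oracles.

test_that("correlation map agrees with brute-force Pearson to 1e-12", {
  set.seed(51)
  for (i in 1:3) {
    x <- matrix(rnorm(20 * 6), 20, 6)
    cm <- correlationMap(x)
    expect_lt(max(abs(cm@matrix - pearsonOracle(x))), 1e-12)
  }
})

test_that("correlation map: duplicates, nulls, planted rho, zero variance", {
  set.seed(52)
  x <- matrix(rnorm(500 * 4), 500, 4)
  x[, 2] <- x[, 1]
  cm <- correlationMap(x)
  expect_equal(cm@matrix[1, 2], 1, tolerance = 1e-12)

  nullX <- matrix(rnorm(10000 * 8), 10000, 8)
  cmN <- correlationMap(nullX)
  offdiag <- cmN@matrix[upper.tri(cmN@matrix)]
  expect_lt(max(abs(offdiag)), 0.05)          # null r ~ N(0, 1/sqrt(n))

  rho <- 0.8
  z <- rnorm(10000)
  planted <- cbind(z, rho * z + sqrt(1 - rho^2) * rnorm(10000))
  expect_equal(correlationMap(planted)@matrix[1, 2], rho, tolerance = 0.05)

  xz <- cbind(x[, 1:2], 5)                    # constant feature
  cmZ <- correlationMap(xz)
  expect_identical(cmZ@zeroVariance, c(FALSE, FALSE, TRUE))
  expect_true(all(is.na(cmZ@matrix[3, ])))
  expect_false(anyNA(cmZ@matrix[1:2, 1:2]))
  expect_error(correlationMap(x[1, , drop = FALSE]), "2 pixels")
})

test_that("uncentered PCA puts the mean on PC1; centered cross-checks prcomp", {
  set.seed(53)
  mu <- runif(30, 5, 10)                      # mean >> variance
  x <- matrix(rep(mu, each = 200), 200) + matrix(rnorm(200 * 30, sd = 0.1), 200)
  pc <- pcaSpectra(x, center = FALSE, nPc = 3)
  cosine <- sum(loadings(pc)[, 1] * mu) / sqrt(sum(mu^2))
  expect_gt(cosine, 0.99)
  expect_gt(varianceFraction(pc)[1], 0.99)

  pcc <- pcaSpectra(x, center = TRUE, nPc = 5)
  pr <- prcomp(x, center = TRUE)
  expect_equal(abs(diag(cor(scores(pcc), pr$x[, 1:5]))), rep(1, 5),
               tolerance = 1e-6)
  expect_equal(varianceFraction(pcc),
               (pr$sdev^2 / sum(pr$sdev^2))[1:5], tolerance = 1e-9)
})

test_that("PCA recovers planted factor structure and reconstructs the data", {
  set.seed(54)
  p <- 40
  f1 <- rnorm(p); f1 <- f1 / sqrt(sum(f1^2))
  f2 <- rnorm(p); f2 <- f2 - sum(f2 * f1) * f1; f2 <- f2 / sqrt(sum(f2^2))
  n <- 2000
  x <- outer(rnorm(n, sd = 2), f1) + outer(rnorm(n, sd = 1), f2) +
    matrix(rnorm(n * p, sd = 0.01), n)
  pc <- pcaSpectra(x, center = TRUE, nPc = 2)
  fr <- varianceFraction(pc)[1:2]
  expect_equal(fr / sum(fr), c(0.8, 0.2), tolerance = 0.02)

  # rank-1 matrix: PC1 carries all the variance
  r1 <- outer(rnorm(50), rnorm(6))
  expect_equal(varianceFraction(pcaSpectra(r1, center = FALSE, nPc = 1))[1], 1,
               tolerance = 1e-9)

  # full reconstruction
  small <- matrix(rnorm(30 * 8), 30, 8)
  for (ctr in c(TRUE, FALSE)) {
    m <- pcaSpectra(small, center = ctr)
    expect_lt(max(abs(pcaReconstruct(m) - small)), 1e-8)
    # loadings orthonormal
    g <- crossprod(loadings(m))
    expect_lt(max(abs(g - diag(ncol(g)))), 1e-9)
  }
})

test_that("HCA leaf order separates blobs and merges duplicates first", {
  set.seed(55)
  a <- matrix(rnorm(10 * 5), 10, 5)
  b <- matrix(rnorm(12 * 5), 12, 5) + 40      # inter/intra ratio >> 10
  x <- rbind(a, b)
  ord <- hcaOrder(x)
  grp <- c(rep(1, 10), rep(2, 12))[ord]
  expect_identical(length(rle(grp)$lengths), 2L)   # each blob contiguous

  dup <- rbind(a, a[1, , drop = FALSE])
  h <- hclust(dist(dup), method = "ward.D2")
  expect_equal(h$height[1], 0)                     # duplicates merge at 0

  perm <- sample(22)
  ord2 <- hcaOrder(x[perm, ])
  expect_identical(length(rle(c(rep(1, 10), rep(2, 12))[perm][ord2])$lengths), 2L)
  expect_error(hcaOrder(x[1, , drop = FALSE]), "2 spectra")
})

test_that("feature K-means recovers separated groups deterministically", {
  set.seed(56)
  n <- 200
  protos <- matrix(rnorm(4 * n, sd = 1), 4)
  protos <- protos * 10
  x <- t(protos[rep(1:4, each = 6), ] + matrix(rnorm(24 * n, sd = 0.1), 24))
  truth <- rep(1:4, each = 6)
  got <- kmeansFeatures(x, K = 4, seed = 3)
  expect_equal(ariIndex(got, truth), 1)
  expect_identical(got, kmeansFeatures(x, K = 4, seed = 3))  # same seed
  # quintupled (identical) columns always co-cluster
  xq <- cbind(x, x[, 1], x[, 1])
  gq <- kmeansFeatures(xq, K = 4, seed = 5)
  expect_identical(gq[25], gq[1])
  expect_identical(gq[26], gq[1])
  expect_error(kmeansFeatures(x[, c(1, 1, 1)], K = 3, seed = 1), "distinct")
})

test_that("double clustering exposes planted block structure on both axes", {
  set.seed(57)
  nPix <- 120L; nF <- 24L
  pixClass <- rep(1:3, each = nPix / 3)
  featClass <- rep(1:4, each = nF / 4)
  # block means chosen so the standardized feature profiles stay distinct
  blockMeans <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(2, 2, 0))
  signal <- t(blockMeans[featClass, pixClass])
  v <- signal + matrix(rnorm(nPix * nF, sd = 0.05), nPix)
  desc <- data.frame(kind = rep(c("wavenumber", "element"), c(16, 8)),
                     wavenumber = c(seq(960, 900, by = -4), rep(NA, 8)),
                     isotope = c(rep(NA, 16), rep(isotopePanel()[1:4], each = 2)),
                     replicate = c(rep(0L, 16), rep(1:2, 4)))
  fused <- new("FusedMatrix", values = v, descriptors = desc,
               coords = cbind(rep(1:12, each = 10), rep(1:10, 12)),
               snr = rep(1000, nPix), tissue = rep(TRUE, nPix))
  dc <- doubleCluster(fused, K = 4, snrThreshold = 500, seed = 2)
  ordClass <- pixClass[dc@spectrumOrder]
  # the three pixel classes come out contiguous in leaf order
  expect_lte(length(rle(ordClass)$lengths), 4L)
  expect_gt(ariIndex(dc@featureAssignment, featClass), 0.9)
  expect_identical(sort(dc@spectrumOrder), 1:nPix)   # a permutation
  expect_identical(dim(dc@sortedMatrix), c(nPix, nF))
  # sorted spectrum is the cluster-ordered unstandardized mean
  expect_equal(dc@sortedSpectrum, colMeans(v)[dc@featureOrder],
               tolerance = 1e-12)
})

test_that("elements co-cluster with a correlated low-wavenumber FTIR band", {
  ce <- neutralClassElements()
  # all nine elements share one latent field with the 960 cm-1 band, the
  # construction behind a joint elements + low-wavenumber feature cluster
  crossAll <- do.call(rbind, lapply(isotopePanel(), function(iso)
    data.frame(isotope = iso, wavenumber = 960, rho = 0.9, latent = 1L)))
  scene <- makeScene(rows = 90, cols = 90, laShape = c(30, 30), theta = 0,
                     wavenumbersAxis = fusedAxis(), thicknessRange = c(1, 1),
                     wvRange = c(0, 0), driftAmplitude = 0, co2Amplitude = 0,
                     ftirNoiseSd = 0.001, bandAmplitude = 0.3,
                     crossCorr = crossAll, classElements = ce, seed = 58)
  cube <- renderFtir(scene)
  img <- standardizeElementImage(
    subtractLaBackground(renderElements(scene), RegionSet(rbind(c(0, 0, 4, 4)))))
  reg <- registerCube(cube, theta = 0, targetShape = c(30, 30))
  fused <- concatenateFeatures(cropInterpolateFtir(reg),
                               flattenElementImage(img),
                               tissue = as.vector(t(tissueMask(img))))
  fused <- standardizeFused(fused, zeroVariance = "keep")
  dc <- doubleCluster(fused, K = 4, snrThreshold = 500, seed = 3)
  d <- featureDescriptors(fused)
  i960 <- which(d$kind == "wavenumber" & d$wavenumber == 960)
  elCluster <- unique(dc@featureAssignment[d$kind == "element"])
  expect_length(elCluster, 1)                  # all elements together
  expect_identical(dc@featureAssignment[i960], elCluster)
})

test_that("cross-block summary flags contamination and respects null bounds", {
  set.seed(59)
  n <- 10000
  wnBlock <- matrix(rnorm(n * 20), n)
  elBlock <- matrix(rnorm(n * 9), n)
  desc <- data.frame(kind = rep(c("wavenumber", "element"), c(20, 9)),
                     wavenumber = c(seq(976, 900, by = -4), rep(NA, 9)),
                     isotope = c(rep(NA, 20), isotopePanel()),
                     replicate = c(rep(0L, 20), rep(1L, 9)))
  cm <- correlationMap(cbind(wnBlock, elBlock), descriptors = desc)
  s <- crossBlockSummary(cm)
  expect_lt(s$crossMax, correlationNullBound(n, s$nCrossPairs))

  # an element column duplicated into the FTIR block -> crossMax = 1
  leak <- cbind(wnBlock[, 1:19], elBlock[, 1], elBlock)
  cmL <- correlationMap(leak, descriptors = desc)
  expect_equal(crossBlockSummary(cmL)$crossMax, 1, tolerance = 1e-12)

  # correlated bands, independent elements: within-FTIR mean > cross mean
  z <- rnorm(n)
  corrBands <- sapply(1:20, function(i) 0.7 * z + sqrt(0.51) * rnorm(n))
  cmB <- correlationMap(cbind(corrBands, elBlock), descriptors = desc)
  sB <- crossBlockSummary(cmB)
  expect_gt(sB$withinFtirMean, sB$crossMean)
})
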
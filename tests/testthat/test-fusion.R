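# Concatenation and normalization of the fused pixel x feature matrix.

test_that("interpolation onto the 226-point grid copies aligned axes", {
  wn <- fullAxis()
  s <- defaultClassSpectra(wn)[2, ]
  cube <- cubeFromSpectra(rbind(s, 2 * s), 1, 2, wn)
  res <- cropInterpolateFtir(cube)
  expect_identical(ncol(res$matrix), 226L)
  expect_identical(res$wavenumbers, seq(1800, 900, by = -4))
  keep <- wn <= 1800 & wn >= 900
  expect_equal(res$matrix[1, ], unname(s[keep]), tolerance = 1e-12)

  # 2 cm-1 axis: every other point
  wn2 <- seq(1800, 900, by = -2)
  cube2 <- cubeFromSpectra(rbind(seq_along(wn2) * 0.01), 1, 1, wn2)
  res2 <- cropInterpolateFtir(cube2)
  expect_identical(ncol(res2$matrix), 226L)
  expect_equal(res2$matrix[1, ], (seq(1, length(wn2), by = 2)) * 0.01,
               tolerance = 1e-12)

  # constant spectrum -> constant row
  cc <- cubeFromSpectra(rbind(rep(4.2, length(wn))), 1, 1, wn)
  expect_equal(unique(as.vector(cropInterpolateFtir(cc)$matrix)), 4.2)

  short <- FtirCube(array(0, dim = c(1, 1, 51)), seq(1100, 900, by = -4))
  expect_error(cropInterpolateFtir(short), "cover")
})

test_that("concatenation yields 226 + 9 x replicate features with provenance", {
  set.seed(41)
  n <- 20
  ftir <- list(matrix = matrix(rnorm(n * 226), n),
               wavenumbers = fusionGrid(),
               coords = cbind(row = rep(1:4, each = 5), col = rep(1:5, 4)))
  el <- list(matrix = matrix(rnorm(n * 9), n), isotopes = isotopePanel(),
             coords = ftir$coords)
  f5 <- concatenateFeatures(ftir, el, replicate = 5)
  expect_identical(ncol(fusedValues(f5)), 271L)
  f1 <- concatenateFeatures(ftir, el, replicate = 1)
  expect_identical(ncol(fusedValues(f1)), 235L)
  d <- featureDescriptors(f5)
  expect_identical(sum(d$kind == "wavenumber"), 226L)
  expect_identical(sum(d$kind == "element"), 45L)
  # replicated columns are exactly equal pre-normalization
  zn <- which(d$isotope == "64Zn")
  expect_length(zn, 5)
  v <- fusedValues(f5)
  for (j in zn[-1]) expect_identical(v[, j], v[, zn[1]])
  # element block sits after the 900 cm-1 end, replicates adjacent
  expect_identical(d$kind[226], "wavenumber")
  expect_identical(d$wavenumber[226], 900)
  expect_identical(d$isotope[227:231], rep("13C", 5))
  expect_identical(d$replicate[227:231], 1:5)

  elShort <- list(matrix = el$matrix[-1, ], isotopes = el$isotopes,
                  coords = el$coords[-1, ])
  expect_error(concatenateFeatures(ftir, elShort), "pixel counts")
  # shuffled isotope input is canonicalized
  sh <- sample(9)
  elSh <- list(matrix = el$matrix[, sh], isotopes = el$isotopes[sh],
               coords = el$coords)
  expect_equal(fusedValues(concatenateFeatures(ftir, elSh, replicate = 2)),
               fusedValues(concatenateFeatures(ftir, el, replicate = 2)))
})

test_that("pixel subsetting commutes with fusion", {
  set.seed(42)
  n <- 12
  ftir <- list(matrix = matrix(rnorm(n * 10), n),
               wavenumbers = seq(936, 900, by = -4),
               coords = cbind(row = rep(1:3, each = 4), col = rep(1:4, 3)))
  el <- list(matrix = matrix(rnorm(n * 9), n), isotopes = isotopePanel(),
             coords = ftir$coords)
  keep <- c(1, 3, 7, 10)
  whole <- subsetPixels(concatenateFeatures(ftir, el), keep)
  part <- concatenateFeatures(
    list(matrix = ftir$matrix[keep, ], wavenumbers = ftir$wavenumbers,
         coords = ftir$coords[keep, ]),
    list(matrix = el$matrix[keep, ], isotopes = el$isotopes,
         coords = el$coords[keep, ]))
  expect_identical(fusedValues(whole), fusedValues(part))
  expect_identical(pixelCoords(whole), pixelCoords(part))
})

test_that("fused background subtraction zeroes the region per feature", {
  set.seed(43)
  n <- 25
  ftir <- list(matrix = matrix(5, n, 8), wavenumbers = seq(928, 900, by = -4),
               coords = cbind(row = rep(1:5, each = 5), col = rep(1:5, 5)))
  el <- list(matrix = matrix(-2, n, 9), isotopes = isotopePanel(),
             coords = ftir$coords)
  fused <- concatenateFeatures(ftir, el)
  rs <- RegionSet(rbind(c(0, 0, 2, 2)), frame = "fused")
  out <- subtractFusedBackground(fused, rs)
  expect_equal(max(abs(fusedValues(out))), 0)   # constant matrix -> zero

  ftir$matrix <- matrix(rnorm(n * 8), n)
  el$matrix <- matrix(rnorm(n * 9), n)
  fused2 <- subtractFusedBackground(concatenateFeatures(ftir, el), rs)
  lin <- (pixelCoords(fused2)[, 1] - 1) * 5 + pixelCoords(fused2)[, 2]
  inRegion <- lin %in% c(1, 2, 6, 7)
  expect_lt(max(abs(colMeans(fusedValues(fused2)[inRegion, ]))), 1e-10)
  bad <- RegionSet(rbind(c(10, 10, 2, 2)), frame = "fused")
  expect_error(subtractFusedBackground(fused, bad), "bounds")
})

test_that("planted no-tissue offsets are removed to within sampling error", {
  scene <- makeScene(rows = 90, cols = 90, laShape = c(30, 30), theta = 0,
                     ftirNoiseSd = 0.001, driftAmplitude = 0.01, seed = 44)
  cube <- renderFtir(scene)
  pp <- preprocessFtir(cube, waterVaporReference(fullAxis()))
  reg <- registerCube(pp$cube, theta = 0, targetShape = c(30, 30))
  img <- renderElements(scene)                    # offsets still present
  fused <- concatenateFeatures(cropInterpolateFtir(reg),
                               flattenElementImage(img))
  rs <- RegionSet(rbind(c(0, 0, 4, 4), c(26, 26, 4, 4)), frame = "fused")
  out <- subtractFusedBackground(fused, rs)
  d <- featureDescriptors(out)
  # element offsets (10, ..., 3) removed: pure-background pixels (away from
  # the tissue boundary, where no partial-volume signal leaks in) are ~0
  co <- pixelCoords(out)
  pure <- (co[, 1] <= 5 | co[, 1] >= 26) & (co[, 2] <= 5 | co[, 2] >= 26)
  for (iso in c("13C", "64Zn")) {
    j <- which(d$isotope == iso & d$replicate == 1)
    sem <- scene@noise$elementSd / sqrt(32)
    expect_lt(abs(mean(fusedValues(out)[pure, j])), 4 * sem)
  }
})

test_that("fused standardization enforces moments and names zero-variance features", {
  set.seed(45)
  n <- 40
  ftir <- list(matrix = matrix(rnorm(n * 12), n),
               wavenumbers = seq(944, 900, by = -4),
               coords = cbind(row = rep(1:8, each = 5), col = rep(1:5, 8)))
  el <- list(matrix = matrix(rnorm(n * 9), n), isotopes = isotopePanel(),
             coords = ftir$coords)
  fused <- concatenateFeatures(ftir, el, replicate = 3)
  out <- standardizeFused(fused)
  v <- fusedValues(out)
  expect_lt(max(abs(colMeans(v))), 1e-10)
  expect_equal(unname(apply(v, 2, sd)), rep(1, ncol(v)), tolerance = 1e-9)
  # affine invariance per feature
  aff <- fused
  aff@values <- sweep(sweep(fused@values, 2, runif(ncol(v), 0.5, 2), "*"),
                      2, rnorm(ncol(v)), "+")
  expect_equal(fusedValues(standardizeFused(aff)), v, tolerance = 1e-9)
  # replicated element columns remain mutually identical
  d <- featureDescriptors(out)
  fe <- which(d$isotope == "56Fe")
  for (j in fe[-1]) expect_equal(v[, j], v[, fe[1]], tolerance = 1e-12)

  flat <- fused
  flat@values[, 3] <- 7
  expect_error(standardizeFused(flat), "wn 936")
  kept <- standardizeFused(flat, zeroVariance = "keep")
  expect_equal(unique(fusedValues(kept)[, 3]), 0)
})
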
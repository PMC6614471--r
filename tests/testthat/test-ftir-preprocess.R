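# The five-step spectral correction chain, each step against its
# constructive oracle.

test_that("water-vapor subtraction recovers clean spectra exactly and zeroes the band", {
  wn <- fullAxis()
  ref <- waterVaporReference(wn)
  clean <- defaultClassSpectra(wn)[2, ]
  linearSpec <- 0.1 + 1e-4 * wn               # exactly zero local band area
  # linear-model identity: s = clean + 0.3 ref
  cube <- cubeFromSpectra(rbind(clean + 0.3 * ref@spectrum, linearSpec), 1, 2, wn)
  out <- subtractWaterVapor(cube, ref)
  m <- spectraFromCube(out)
  expect_lt(max(abs(m[1, ] - clean)), 1e-10)
  # spectrum with zero band area is untouched (k = 0)
  expect_lt(max(abs(m[2, ] - linearSpec)), 1e-10)
  # output band area (local-line corrected) is 0
  expect_lt(abs(trapzOracle(m[1, ], wn, 1860, 1878, localLine = TRUE)), 1e-10)
})

test_that("per-pixel random vapor coefficients are removed across a cube", {
  wn <- fullAxis()
  ref <- waterVaporReference(wn)
  scene <- makeScene(rows = 32, cols = 32, laShape = c(8, 8), theta = 0,
                     thicknessRange = c(1, 1), driftAmplitude = 0,
                     ftirNoiseSd = 0, co2Amplitude = 0, wvRange = c(0, 1),
                     seed = 7)
  cube <- renderFtir(scene)
  clean <- renderFtir(scene, clean = TRUE)
  out <- subtractWaterVapor(cube, ref)
  # direct-subtraction oracle using the stored ground-truth coefficients
  kTrue <- as.vector(t(scene@wvCoeffField))
  oracle <- spectraFromCube(cube) - outer(kTrue, ref@spectrum)
  expect_lt(max(abs(spectraFromCube(out) - oracle)), 1e-8)
  expect_lt(max(abs(spectraFromCube(out) - spectraFromCube(clean))), 1e-8)
})

test_that("vapor reference with zero band area or mismatched axis errors", {
  wn <- fullAxis()
  cube <- FtirCube(array(1, dim = c(2, 2, length(wn))), wn)
  flat <- WaterVaporReference(rep(1, length(wn)), wn)
  expect_error(subtractWaterVapor(cube, flat), "zero")
  other <- waterVaporReference(wn + 1)
  expect_error(subtractWaterVapor(cube, other), "axis")
})

test_that("CO2 removal replaces the band by a line, preserves endpoints, idempotent", {
  wn <- fullAxis()
  base <- 0.2 + 0.0001 * (wn - 2350)          # linear on the band
  spike <- base + 0.5 * exp(-((wn - 2350)^2) / (2 * 25^2))
  cube <- cubeFromSpectra(rbind(base, spike), 1, 2, wn)
  out <- removeCO2(cube)
  m <- spectraFromCube(out)
  expect_lt(max(abs(m[1, ] - base)), 1e-12)   # already linear: unchanged
  inside <- wn < 2450 & wn > 2250
  # oracle: line joining the spike spectrum's own endpoint values
  iHi <- which.min(abs(wn - 2450)); iLo <- which.min(abs(wn - 2250))
  w <- (wn[inside] - wn[iLo]) / (wn[iHi] - wn[iLo])
  lineOracle <- spike[iLo] * (1 - w) + spike[iHi] * w
  expect_lt(max(abs(m[2, inside] - lineOracle)), 1e-12)
  # the 0.5-high spike is gone; values outside the band untouched
  expect_lt(max(m[2, inside] - base[inside]), 0.001)
  expect_identical(m[2, !inside], spike[!inside])
  expect_equal(absorbance(removeCO2(out)), absorbance(out))  # idempotent
  shortWn <- seq(1800, 900, by = -4)
  shortCube <- FtirCube(array(1, dim = c(1, 1, length(shortWn))), shortWn)
  expect_warning(removeCO2(shortCube), "unchanged")
})

test_that("amide scaling enforces the target area and removes thickness variation", {
  wn <- fullAxis()
  s <- defaultClassSpectra(wn)[3, ]
  cube <- cubeFromSpectra(rbind(s, 1.3 * s), 1, 2, wn)
  res <- scaleAmide(cube, targetArea = 100)
  m <- spectraFromCube(res$cube)
  a1 <- trapzOracle(m[1, ], wn, 1490, 1730)
  expect_equal(a1, 100, tolerance = 1e-9)
  # thickness-factor invariance
  expect_lt(max(abs(m[1, ] - m[2, ])), 1e-10)
  expect_true(all(res$usable))

  scene <- makeScene(rows = 32, cols = 32, laShape = c(8, 8), theta = 0,
                     wvRange = c(0, 0), driftAmplitude = 0, ftirNoiseSd = 0,
                     co2Amplitude = 0, thicknessRange = c(0.8, 1.2), seed = 8)
  sc <- scaleAmide(renderFtir(scene), targetArea = 100)
  areas <- apply(spectraFromCube(sc$cube)[as.vector(t(classMap(scene) > 0)), ],
                 1, trapzOracle, wn = wavenumbers(sc$cube), lo = 1490, hi = 1730)
  expect_lt(sd(areas), 1e-9)                  # SD of amide areas = 0
  # the un-scaled cube varies with the thickness field
  raw <- apply(spectraFromCube(renderFtir(scene))[as.vector(t(classMap(scene) > 0)), ],
               1, trapzOracle, wn = fullAxis(), lo = 1490, hi = 1730)
  expect_gt(sd(raw), 1)
})

test_that("non-positive amide areas are flagged unusable, not scaled", {
  wn <- fullAxis()
  s <- defaultClassSpectra(wn)[2, ]
  cube <- cubeFromSpectra(rbind(s, -s, 0 * s), 1, 3, wn)
  res <- scaleAmide(cube)
  expect_identical(as.vector(t(res$usable)), c(TRUE, FALSE, FALSE))
  m <- spectraFromCube(res$cube)
  expect_identical(m[2, ], -s)                # untouched
})

test_that("baseline subtraction annihilates piecewise-linear spectra and zeroes anchors", {
  wn <- fullAxis()
  anchors <- baselineAnchors()
  aIdx <- vapply(anchors, function(a) which.min(abs(wn - a)), integer(1))
  # spectrum that is itself piecewise-linear through the anchors
  set.seed(9)
  vals <- rnorm(length(anchors))
  pw <- approx(wn[aIdx], vals, xout = wn, rule = 2)$y
  cube <- cubeFromSpectra(rbind(pw, rep(3.2, length(wn))), 1, 2, wn)
  out <- spectraFromCube(subtractBaseline(cube))
  rng <- wn <= 3900 & wn >= 900
  expect_lt(max(abs(out[1, rng])), 1e-10)
  expect_lt(max(abs(out[2, rng])), 1e-12)     # constant spectrum -> 0
  outside <- wn > 3900
  expect_identical(out[2, outside], rep(3.2, sum(outside)))
  # anchor sweep on a random cube
  rc <- FtirCube(array(rnorm(4 * 3 * length(wn)), dim = c(4, 3, length(wn))), wn)
  bm <- spectraFromCube(subtractBaseline(rc))
  expect_lt(max(abs(bm[, aIdx])), 1e-12)
  expect_error(subtractBaseline(rc, anchors = c(4100, anchors)), "4100")
})

test_that("SNR matches the Monte-Carlo h/sigma oracle and sentinels", {
  wn <- fullAxis()
  h <- 0.5; sigma <- 0.002
  peak <- h * exp(-((wn - 1655)^2) / (2 * 25^2))
  set.seed(10)
  reps <- 400
  noisy <- matrix(rep(peak, each = reps), reps) +
    matrix(rnorm(reps * length(wn), sd = sigma), reps)
  cube <- cubeFromSpectra(noisy, reps, 1, wn)
  snr <- snrValues(computeSnr(cube))
  expect_equal(mean(snr), h / sigma, tolerance = 0.15)
  # noiseless spectrum (exactly flat in the noise window) -> Inf sentinel
  tri <- pmax(0, 1 - abs(wn - 1655) / 40)
  clean <- cubeFromSpectra(rbind(tri), 1, 1, wn)
  expect_identical(as.vector(snrValues(computeSnr(clean))), Inf)
})

test_that("the SNR threshold separates generator-planted quality classes", {
  wn <- fullAxis()
  peak <- exp(-((wn - 1655)^2) / (2 * 25^2))
  set.seed(11)
  n <- 50
  hi <- matrix(rep(peak, each = n), n) + matrix(rnorm(n * 826, sd = 1 / 600), n)
  lo <- matrix(rep(peak, each = n), n) + matrix(rnorm(n * 826, sd = 1 / 60), n)
  cube <- cubeFromSpectra(rbind(hi, lo), 100, 1, wn)
  mask <- snrMask(computeSnr(cube, threshold = 150))
  expect_identical(as.vector(mask), rep(c(TRUE, FALSE), each = n))
})

test_that("ratio images flag masked pixels and rank tissue classes correctly", {
  wn <- fullAxis()
  b1230 <- exp(-((wn - 1230)^2) / (2 * 30^2))
  b1655 <- exp(-((wn - 1655)^2) / (2 * 25^2))
  cube <- cubeFromSpectra(rbind(2 * b1230 + b1655, 2 * b1230 + b1655), 1, 2, wn)
  r <- ratioImage(cube, 1230, 1655)
  expect_equal(as.vector(r), c(2, 2), tolerance = 0.01)  # band-tail overlap
  snr <- new("SnrMap", snr = matrix(c(200, 10), 1, 2), threshold = 150)
  r2 <- ratioImage(cube, 1230, 1655, snrMap = snr)
  expect_true(is.na(r2[1, 2]) && !is.na(r2[1, 1]))

  scene <- makeScene(rows = 48, cols = 48, laShape = c(12, 12), theta = 0,
                     ftirNoiseSd = 0.001, seed = 12)
  pp <- preprocessFtir(renderFtir(scene), waterVaporReference(fullAxis()))
  rat <- ratioImage(pp$cube, 1230, 1655, snrMap = pp$snr)
  cm <- classMap(scene)
  # epithelium (phosphate-rich) shows a higher A1230/A1655 than stroma
  expect_gt(mean(rat[cm == 2], na.rm = TRUE), mean(rat[cm == 1], na.rm = TRUE))
})

test_that("preprocessing is per-pixel independent and scaling is checked mid-chain", {
  wn <- fullAxis()
  set.seed(13)
  spectra <- defaultClassSpectra(wn)[sample(2:4, 12, replace = TRUE), ] +
    matrix(rnorm(12 * length(wn), sd = 0.01), 12)
  cube <- cubeFromSpectra(spectra, 3, 4, wn)
  perm <- sample(12)
  cubeP <- cubeFromSpectra(spectra[perm, ], 3, 4, wn)
  out <- spectraFromCube(subtractBaseline(cube))
  outP <- spectraFromCube(subtractBaseline(cubeP))
  expect_equal(outP, out[perm, ])             # permutation equivariance

  ref <- waterVaporReference(wn)
  pp <- preprocessFtir(cube, ref, targetArea = 100)
  # after the final baseline step the amide area is no longer the target...
  areas <- apply(spectraFromCube(pp$cube), 1, trapzOracle, wn = wn,
                 lo = 1490, hi = 1730)
  expect_false(isTRUE(all.equal(mean(areas), 100, tolerance = 0.01)))
  # ...but it was exactly the target right after the scaling step
  mid <- scaleAmide(removeCO2(subtractWaterVapor(cube, ref)), 100)
  midAreas <- apply(spectraFromCube(mid$cube), 1, trapzOracle, wn = wn,
                    lo = 1490, hi = 1730)
  expect_equal(max(abs(midAreas - 100)), 0, tolerance = 1e-9)
})
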
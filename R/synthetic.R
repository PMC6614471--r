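# Synthetic paired FTIR / LA-ICP-MS scenes with full ground truth: a shared
# tissue layout (stroma with epithelium-lined ducts), per-class Gaussian-band
# endmember spectra and element abundances, every corrupting field the
# preprocessing chain removes (thickness, baseline drift, water vapor, CO2,
# noise), a known rotation offset between the two frames, and optional
# planted correlations with stored latent fields.

.gaussBands <- function(wn, centers, amps, widths) {
  s <- numeric(length(wn))
  for (i in seq_along(centers))
    s <- s + amps[i] * exp(-((wn - centers[i])^2) / (2 * widths[i]^2))
  s
}

## smooth random field in [-1, 1]: a few random low-frequency 2D cosines
.smoothField <- function(rows, cols, nWaves = 4) {
  f <- matrix(0, rows, cols)
  r <- (seq_len(rows) - 1) / max(rows - 1, 1)
  c <- (seq_len(cols) - 1) / max(cols - 1, 1)
  for (i in seq_len(nWaves)) {
    kr <- stats::runif(1, 0.5, 2.5); kc <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + outer(cos(2 * pi * kr * r + ph[1]),
                   cos(2 * pi * kc * c + ph[2]))
  }
  f / max(abs(f))
}

## hi-res index -> LA-grid index along one axis (pixel-center block mapping)
.blockIndex <- function(nHi, nLo) pmin(pmax(ceiling(seq_len(nHi) * nLo / nHi), 1L), nLo)

## forward-rotated LA-grid indices of every FTIR pixel (row-major lists)
.ftirToLaIndex <- function(rows, cols, laShape, theta) {
  th <- theta * pi / 180
  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  r <- rep(seq_len(rows), times = cols) - cy
  c <- rep(seq_len(cols), each = rows) - cx
  dr <- cos(th) * r - sin(th) * c + cy
  dc <- sin(th) * r + cos(th) * c + cx
  lr <- ceiling(dr * laShape[1] / rows)
  lc <- ceiling(dc * laShape[2] / cols)
  ok <- lr >= 1 & lr <= laShape[1] & lc >= 1 & lc <= laShape[2]
  list(row = lr, col = lc, ok = ok)            # column-major pixel order
}

#' Default per-class element abundances
#'
#' Rows: background, stroma, epithelium, duct lumen; columns: the canonical
#' nine isotopes, in arbitrary counts on the scale of typical
#' background-subtracted maps. The default abundances are identical across
#' the tissue classes: on real sections the element distributions are
#' heterogeneous but carry no significant correlation with the infrared
#' markers, so within-tissue element structure comes from the generator's
#' independent per-element heterogeneity fields rather than from the class
#' map. Class-contrasted panels can be passed to \code{\link{makeScene}}
#' explicitly.
#'
#' @return 4 x 9 numeric matrix.
#' @export
defaultClassElements <- function() {
  tissue <- c(5, 2, 3, 1, 1, 2, 1, 1.5, 4)
  m <- rbind(background = numeric(9),
             stroma = tissue, epithelium = tissue, lumen = tissue)
  colnames(m) <- isotopePanel()
  m
}

#' Default per-class endmember spectra
#'
#' Gaussian absorption bands (widths 15-40 cm-1) on the given axis: amide I
#' (~1655), amide II (~1545), CH stretch (~2925), phosphate (~1230), the
#' sugar region (1070/1020) and a glycosylation band near 960 cm-1.
#' Epithelium carries more phosphate than stroma; the duct lumen is a weak
#' echo of stroma; background is zero.
#'
#' @param wn wavenumber axis.
#' @return 4 x length(wn) matrix (background, stroma, epithelium, lumen).
#' @export
defaultClassSpectra <- function(wn) {
  centers <- c(2925, 1655, 1545, 1455, 1230, 1070, 1020, 960)
  widths  <- c(35,   28,   30,   22,   30,   25,   20,   18)
  stroma  <- c(0.15, 0.80, 0.45, 0.12, 0.10, 0.10, 0.08, 0.04)
  epith   <- c(0.18, 0.85, 0.50, 0.14, 0.25, 0.15, 0.10, 0.08)
  m <- rbind(background = numeric(length(wn)),
             stroma     = .gaussBands(wn, centers, stroma, widths),
             epithelium = .gaussBands(wn, centers, epith, widths),
             lumen      = 0.15 * .gaussBands(wn, centers, stroma, widths))
  m
}

#' Deterministic water-vapor reference spectrum
#'
#' A comb of narrow (4-6 cm-1) rotational-vibrational lines over 2000-1300
#' and 3900-3550 cm-1, with a line inside the 1878-1860 cm-1 reference band
#' so the subtraction coefficient is well defined.
#'
#' @param wn wavenumber axis.
#' @param band reference band, default \code{c(1878, 1860)}.
#' @return A \linkS4class{WaterVaporReference}.
#' @export
waterVaporReference <- function(wn, band = c(1878, 1860)) {
  lines1 <- seq(1990, 1310, by = -17)
  lines2 <- seq(3890, 3560, by = -23)
  centers <- c(lines1, 1869, lines2)
  amps <- c(0.5 + 0.5 * abs(sin(seq_along(lines1) * 1.7)), 1.0,
            0.3 + 0.3 * abs(cos(seq_along(lines2) * 2.3)))
  widths <- rep(c(4, 5, 6), length.out = length(centers))
  WaterVaporReference(.gaussBands(wn, centers, amps, widths), wn, band = band)
}

#' Generate a synthetic paired scene
#'
#' Builds the ground-truth description of a duct-structured tissue section
#' observed by both modalities. The tissue is an elliptical blob of stroma
#' (fraction of the frame about 0.3-0.7) containing \code{nDucts}
#' epithelium-lined duct lumina. All random draws are taken here under
#' \code{seed}; the renderers are pure functions of the scene.
#'
#' @param rows,cols FTIR grid (default 128 x 128 at 6.25 um).
#' @param laShape elemental grid, default \code{c(41, 41)} (~19.5 um pixels
#'   over the same field).
#' @param wavenumbersAxis FTIR axis, default 4000..700 cm-1 at 4 cm-1 (826
#'   points).
#' @param nDucts number of ducts, default 3.
#' @param theta true rotation offset in degrees between the FTIR and
#'   elemental frames, default 2.
#' @param thicknessRange multiplicative section-thickness range, default
#'   \code{c(0.8, 1.2)}.
#' @param wvRange per-pixel water-vapor coefficient range, default
#'   \code{c(0, 0.3)}.
#' @param driftAmplitude baseline drift amplitude (absorbance), default 0.02.
#' @param ftirNoiseSd i.i.d. absorbance noise SD, default 0.002.
#' @param elementNoiseSd i.i.d. element noise SD (counts), default 0.2.
#' @param elementOffsets per-element additive background offset, default a
#'   fixed positive vector.
#' @param elementHeterogeneity amplitude (counts) of smooth per-element
#'   abundance variation across the tissue, independent of the class map
#'   (the two modalities stay orthogonal); default 0.5.
#' @param co2Amplitude CO2 band amplitude, default 0.05.
#' @param bandAmplitude amplitude of planted-correlation bands, default 0.1.
#' @param crossCorr data.frame(isotope, wavenumber, rho) of planted
#'   cross-modal correlations; default none (the modalities are orthogonal,
#'   as observed on real tissue).
#' @param ftirCorr data.frame(wavenumber1, wavenumber2, rho) of planted
#'   within-FTIR correlations; default none.
#' @param classElements optional 4 x 9 abundance matrix override.
#' @param classSpectra optional 4 x n_wn endmember override.
#' @param seed integer master seed.
#' @return A \linkS4class{SyntheticScene}.
#' @export
makeScene <- function(rows = 128, cols = 128, laShape = c(41, 41),
                      wavenumbersAxis = seq(4000, 700, by = -4),
                      nDucts = 3, theta = 2,
                      thicknessRange = c(0.8, 1.2), wvRange = c(0, 0.3),
                      driftAmplitude = 0.02, ftirNoiseSd = 0.002,
                      elementNoiseSd = 0.2, elementOffsets = NULL,
                      elementHeterogeneity = 0.5,
                      co2Amplitude = 0.05, bandAmplitude = 0.1,
                      crossCorr = NULL, ftirCorr = NULL,
                      classElements = NULL, classSpectra = NULL, seed = 1) {
  if (rows < 32 || cols < 32) stop("scene grid must be at least 32 x 32")
  laShape <- as.integer(laShape)
  wn <- as.numeric(wavenumbersAxis)
  if (is.null(crossCorr))
    crossCorr <- data.frame(isotope = character(), wavenumber = numeric(),
                            rho = numeric())
  if (is.null(ftirCorr))
    ftirCorr <- data.frame(wavenumber1 = numeric(), wavenumber2 = numeric(),
                           rho = numeric())
  if (is.null(classElements)) classElements <- defaultClassElements()
  if (is.null(classSpectra)) classSpectra <- defaultClassSpectra(wn)
  if (is.null(elementOffsets))
    elementOffsets <- c(10, 4, 6, 1, 1, 2, 1, 1.5, 3)
  bad <- setdiff(crossCorr$isotope, isotopePanel())
  if (length(bad)) stop("unknown isotope in crossCorr: ", paste(bad, collapse = ", "))

  .withSeed(seed, {
    # class map: elliptical stroma blob with epithelium-ringed duct lumina
    cm <- matrix(0L, rows, cols)
    cy <- rows / 2; cx <- cols / 2
    ay <- 0.42 * rows; ax <- 0.45 * cols
    rr <- matrix(rep(seq_len(rows), cols), rows, cols)
    cc <- matrix(rep(seq_len(cols), each = rows), rows, cols)
    inside <- ((rr - cy) / ay)^2 + ((cc - cx) / ax)^2 <= 1
    cm[inside] <- 1L
    if (nDucts > 0) {
      rl <- 0.055 * min(rows, cols)       # lumen radius
      re <- rl + 0.045 * min(rows, cols)  # outer epithelium radius
      for (i in seq_len(nDucts)) {
        dy <- cy + stats::runif(1, -0.55, 0.55) * ay
        dx <- cx + stats::runif(1, -0.55, 0.55) * ax
        dist <- sqrt((rr - dy)^2 + (cc - dx)^2)
        ring <- dist <= re & dist > rl & inside
        lum <- dist <= rl & inside
        cm[ring] <- 2L
        cm[lum] <- 3L
      }
    }
    thickness <- {
      f <- .smoothField(rows, cols)
      mid <- mean(thicknessRange)
      half <- diff(thicknessRange) / 2
      pmin(pmax(mid + half * f, thicknessRange[1]), thicknessRange[2])
    }
    wv <- matrix(stats::runif(rows * cols, wvRange[1], wvRange[2]), rows, cols)
    latents <- list(
      driftOffset = .smoothField(rows, cols),
      driftSlope = .smoothField(rows, cols),
      co2Field = matrix(stats::runif(rows * cols, 0.5, 1), rows, cols),
      ftirNoiseSeed = sample.int(2^30, 1),
      elementNoiseSeed = sample.int(2^30, 1))
    if (nrow(ftirCorr)) {
      latents$ftirL <- lapply(seq_len(nrow(ftirCorr)), function(i)
        matrix(stats::rnorm(rows * cols), rows, cols))
      latents$ftirW <- lapply(seq_len(nrow(ftirCorr)), function(i)
        matrix(stats::rnorm(rows * cols), rows, cols))
    }
    if (nrow(crossCorr)) {
      # rows may share one latent field via an optional integer "latent"
      # group column (so several elements and one band can co-vary); the
      # mixing noise W is always per row
      groups <- if ("latent" %in% names(crossCorr)) crossCorr$latent
                else seq_len(nrow(crossCorr))
      latents$crossGroup <- as.integer(groups)
      latents$crossL <- lapply(unique(as.integer(groups)), function(g)
        matrix(stats::rnorm(prod(laShape)), laShape[1], laShape[2]))
      names(latents$crossL) <- as.character(unique(as.integer(groups)))
      latents$crossW <- lapply(seq_len(nrow(crossCorr)), function(i)
        matrix(stats::rnorm(prod(laShape)), laShape[1], laShape[2]))
    }
    if (elementHeterogeneity > 0) {
      latents$elementHet <- lapply(seq_len(length(isotopePanel())), function(e)
        elementHeterogeneity * .smoothField(laShape[1], laShape[2]))
    }
    new("SyntheticScene", classMap = cm, wavenumbers = wn,
        classSpectra = unname(classSpectra),
        classElements = unname(classElements), isotopes = isotopePanel(),
        crossCorr = crossCorr, ftirCorr = ftirCorr,
        thicknessField = thickness, wvCoeffField = wv,
        theta = as.numeric(theta), laShape = laShape,
        noise = list(ftirSd = ftirNoiseSd, elementSd = elementNoiseSd,
                     elementOffsets = elementOffsets,
                     driftAmplitude = driftAmplitude,
                     co2Amplitude = co2Amplitude,
                     bandAmplitude = bandAmplitude),
        latents = latents, seed = as.integer(seed))
  })
}

## planted-band spectral shapes on the scene axis
.plantBand <- function(wn, center, amp) .gaussBands(wn, center, amp, 18)

## per-pixel planted FTIR band amplitudes (column-major pixel vectors)
.ftirPlantAmplitudes <- function(scene) {
  rows <- nrow(scene@classMap); cols <- ncol(scene@classMap)
  tissue <- as.numeric(scene@classMap > 0)
  out <- list()
  fc <- scene@ftirCorr
  for (i in seq_len(nrow(fc))) {
    L <- as.vector(scene@latents$ftirL[[i]])
    W <- as.vector(scene@latents$ftirW[[i]])
    rho <- fc$rho[i]
    out[[length(out) + 1]] <- list(
      wavenumber = fc$wavenumber1[i], amp = L * tissue)
    out[[length(out) + 1]] <- list(
      wavenumber = fc$wavenumber2[i],
      amp = (rho * L + sqrt(1 - rho^2) * W) * tissue)
  }
  cx <- scene@crossCorr
  if (nrow(cx)) {
    map <- .ftirToLaIndex(rows, cols, scene@laShape, scene@theta)
    grp <- scene@latents$crossGroup
    combos <- unique(data.frame(wavenumber = cx$wavenumber, group = grp))
    for (i in seq_len(nrow(combos))) {
      Lla <- scene@latents$crossL[[as.character(combos$group[i])]]
      amp <- numeric(rows * cols)
      amp[map$ok] <- Lla[cbind(map$row[map$ok], map$col[map$ok])]
      out[[length(out) + 1]] <- list(wavenumber = combos$wavenumber[i],
                                     amp = amp * tissue)
    }
  }
  out
}

#' Render the FTIR modality of a scene
#'
#' Per pixel: thickness x (class endmember + planted bands), plus smooth
#' baseline drift, the water-vapor reference scaled by the per-pixel
#' coefficient, a CO2 bump at 2350 cm-1 and i.i.d. Gaussian noise. With
#' \code{clean = TRUE} the uncorrupted ground-truth cube (class spectra plus
#' planted bands, unit thickness, no drift/vapor/CO2/noise) is returned.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param clean return the ground-truth cube instead of the observation.
#' @return An \linkS4class{FtirCube}.
#' @export
renderFtir <- function(scene, clean = FALSE) {
  stopifnot(is(scene, "SyntheticScene"))
  rows <- nrow(scene@classMap); cols <- ncol(scene@classMap)
  wn <- scene@wavenumbers
  cls <- as.vector(scene@classMap)             # column-major
  m <- scene@classSpectra[cls + 1L, , drop = FALSE]
  for (pl in .ftirPlantAmplitudes(scene)) {
    g <- .plantBand(wn, pl$wavenumber, scene@noise$bandAmplitude)
    m <- m + outer(pl$amp, g)
  }
  if (!clean) {
    wvRef <- waterVaporReference(wn)
    thick <- as.vector(scene@thicknessField)
    drift <- scene@noise$driftAmplitude *
      (outer(as.vector(scene@latents$driftOffset), rep(1, length(wn))) +
       outer(as.vector(scene@latents$driftSlope), (wn - 2400) / 1500))
    co2 <- outer(scene@noise$co2Amplitude * as.vector(scene@latents$co2Field),
                 .gaussBands(wn, 2350, 1, 25))
    m <- m * thick + drift +
      outer(as.vector(scene@wvCoeffField), wvRef@spectrum) + co2
    if (scene@noise$ftirSd > 0) {
      m <- m + .withSeed(scene@latents$ftirNoiseSeed,
                         matrix(stats::rnorm(length(m), sd = scene@noise$ftirSd),
                                nrow(m), ncol(m)))
    }
  }
  FtirCube(array(m, dim = c(rows, cols, length(wn))), wn, pixelSize = 6.25)
}

## ground-truth class layout in the elemental frame: rotated class map and
## its block-majority downsampling onto the LA grid
.laClassLayout <- function(scene) {
  rows <- nrow(scene@classMap); cols <- ncol(scene@classMap)
  rot <- .rotateMatrixNearest(scene@classMap, scene@theta, fill = 0L)
  ri <- .blockIndex(rows, scene@laShape[1])
  ci <- .blockIndex(cols, scene@laShape[2])
  blockId <- outer(ri, ci, function(a, b) (b - 1L) * scene@laShape[1] + a)
  list(rot = rot, blockId = blockId)
}

#' Ground-truth tissue mask on the elemental grid
#'
#' Fraction of each LA-grid block covered by tissue (any non-background
#' class) after the true rotation; a block is tissue when the fraction
#' exceeds 0.5.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @return Logical laShape matrix.
#' @export
sceneLaTissue <- function(scene) {
  lay <- .laClassLayout(scene)
  frac <- tapply(as.vector(lay$rot > 0), as.vector(lay$blockId), mean)
  full <- numeric(prod(scene@laShape))
  full[as.integer(names(frac))] <- frac
  matrix(full, scene@laShape[1], scene@laShape[2]) > 0.5
}

#' Render the elemental modality of a scene
#'
#' The class map is rotated by the true offset into the elemental frame and
#' block-averaged onto the LA grid; per-element class abundances, planted
#' cross-modal latent contributions (on tissue blocks), the per-element
#' additive background offset and i.i.d. Gaussian noise are then applied.
#' With \code{clean = TRUE} offsets and noise are omitted.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param clean omit background offsets and noise.
#' @return An \linkS4class{ElementImage} on the LA grid.
#' @export
renderElements <- function(scene, clean = FALSE) {
  stopifnot(is(scene, "SyntheticScene"))
  lay <- .laClassLayout(scene)
  nEl <- length(scene@isotopes)
  la <- scene@laShape
  a <- array(0, dim = c(la[1], la[2], nEl))
  id <- as.vector(lay$blockId)
  for (e in seq_len(nEl)) {
    ab <- scene@classElements[as.vector(lay$rot) + 1L, e]
    m <- tapply(ab, id, mean)
    full <- numeric(prod(la))
    full[as.integer(names(m))] <- m
    a[, , e] <- matrix(full, la[1], la[2])
  }
  tissueLa <- sceneLaTissue(scene)
  if (!is.null(scene@latents$elementHet)) {
    for (e in seq_len(nEl))
      a[, , e] <- a[, , e] + scene@latents$elementHet[[e]] * tissueLa
  }
  cx <- scene@crossCorr
  for (i in seq_len(nrow(cx))) {
    e <- match(cx$isotope[i], scene@isotopes)
    rho <- cx$rho[i]
    L <- scene@latents$crossL[[as.character(scene@latents$crossGroup[i])]]
    contrib <- rho * L + sqrt(1 - rho^2) * scene@latents$crossW[[i]]
    a[, , e] <- a[, , e] + contrib * tissueLa
  }
  if (!clean) {
    for (e in seq_len(nEl)) a[, , e] <- a[, , e] + scene@noise$elementOffsets[e]
    if (scene@noise$elementSd > 0) {
      a <- a + .withSeed(scene@latents$elementNoiseSeed,
                         array(stats::rnorm(length(a), sd = scene@noise$elementSd),
                               dim = dim(a)))
    }
  }
  ElementImage(a, isotopes = scene@isotopes,
               pixelSize = 6.25 * nrow(scene@classMap) / la[1])
}
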
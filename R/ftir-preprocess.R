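# The five-step per-spectrum FTIR correction chain, applied in the fixed
# sequence: water vapor -> CO2 -> amide scaling -> baseline -> SNR filter.
# Every operation is per-pixel independent; cubes are flattened to
# pixel x wavenumber matrices internally.

#' WaterVaporReference: reference vapor spectrum for atmospheric subtraction
#'
#' @slot spectrum absorbance on the target cube's axis.
#' @slot wavenumbers the axis (must equal the cube's).
#' @slot band the two-point reference interval (default 1878-1860 cm-1)
#'   whose local-baseline-corrected area fixes the subtraction coefficient.
#' @exportClass WaterVaporReference
setClass("WaterVaporReference",
  representation(spectrum = "numeric", wavenumbers = "numeric",
                 band = "numeric"),
  prototype(band = c(1878, 1860)))

setValidity("WaterVaporReference", function(object) {
  if (length(object@spectrum) != length(object@wavenumbers))
    return("spectrum and axis lengths differ")
  if (length(object@band) != 2) return("band must have two endpoints")
  TRUE
})

#' Construct a WaterVaporReference
#'
#' @param spectrum numeric absorbance vector.
#' @param wavenumbers matching axis in cm-1.
#' @param band reference band endpoints, default \code{c(1878, 1860)}.
#' @return A \linkS4class{WaterVaporReference}.
#' @export
WaterVaporReference <- function(spectrum, wavenumbers, band = c(1878, 1860)) {
  new("WaterVaporReference", spectrum = as.numeric(spectrum),
      wavenumbers = as.numeric(wavenumbers), band = as.numeric(band))
}

#' Default baseline anchor wavenumbers
#'
#' The fourteen anchor points of the piecewise-linear baseline, stored in
#' strictly descending order (the interpolation knots must be monotonic).
#'
#' @return Numeric vector of anchor wavenumbers in cm-1.
#' @export
baselineAnchors <- function() {
  c(3900, 3800, 3666, 3116, 3000, 2700, 1800, 1490, 1422, 1358, 1138, 1114,
    980, 900)
}

#' Subtract the water-vapor contribution from every pixel spectrum
#'
#' For each spectrum s the subtraction coefficient is
#' k = area(s, band) / area(ref, band), where the band area is a trapezoidal
#' integral taken after removing the straight line joining the band's two
#' endpoint absorbances (a local two-point baseline, which makes k
#' insensitive to broad sample baselines). The output is s - k * ref, whose
#' band area is zero by construction.
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param ref a \linkS4class{WaterVaporReference} on the same axis.
#' @return The corrected \linkS4class{FtirCube}.
#' @export
subtractWaterVapor <- function(cube, ref) {
  stopifnot(is(cube, "FtirCube"), is(ref, "WaterVaporReference"))
  wn <- cube@wavenumbers
  if (length(ref@wavenumbers) != length(wn) ||
      max(abs(ref@wavenumbers - wn)) > 1e-9)
    stop("water-vapor reference axis does not match the cube axis")
  idx <- .wnWindow(wn, min(ref@band), max(ref@band))
  refArea <- .localLineArea(matrix(ref@spectrum, nrow = 1), wn, idx)
  if (abs(refArea) < .Machine$double.eps * 100)
    stop("reference water-vapor band area is zero")
  d <- dim(cube@absorbance)
  m <- .flattenPixels(cube@absorbance)
  k <- .localLineArea(m, wn, idx) / refArea
  out <- m - outer(k, ref@spectrum)
  initialize(cube, absorbance = .unflattenPixels(out, d[1], d[2]))
}

#' Replace the CO2 band by a straight line
#'
#' Grid points strictly inside the 2450-2250 cm-1 interval are replaced by
#' linear interpolation between the absorbances at the grid points nearest
#' to the interval endpoints; everything else is untouched. The operation is
#' idempotent. If the axis does not cover the band, the cube is returned
#' unchanged with a warning.
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param band interval endpoints, default \code{c(2450, 2250)}.
#' @return The corrected \linkS4class{FtirCube}.
#' @export
removeCO2 <- function(cube, band = c(2450, 2250)) {
  stopifnot(is(cube, "FtirCube"))
  wn <- cube@wavenumbers
  lo <- min(band); hi <- max(band)
  if (min(wn) > lo || max(wn) < hi) {
    warning("axis does not cover the CO2 band; cube returned unchanged")
    return(cube)
  }
  iHi <- .wnIndex(wn, hi)
  iLo <- .wnIndex(wn, lo)
  inner <- setdiff(.wnWindow(wn, lo, hi), c(iHi, iLo))
  if (length(inner) == 0) return(cube)
  d <- dim(cube@absorbance)
  m <- .flattenPixels(cube@absorbance)
  w <- (wn[inner] - wn[iLo]) / (wn[iHi] - wn[iLo])
  m[, inner] <- m[, iLo] %o% (1 - w) + m[, iHi] %o% w
  initialize(cube, absorbance = .unflattenPixels(m, d[1], d[2]))
}

#' Scale every spectrum to a common amide I + II band area
#'
#' Each spectrum is multiplied by \code{targetArea} divided by its
#' trapezoidal area between 1730 and 1490 cm-1, removing section-thickness
#' variation. The target value is arbitrary; any positive constant yields
#' the same downstream analyses after standardization. Pixels whose amide
#' area is not positive cannot be scaled and are flagged unusable.
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param targetArea positive target band area (absorbance * cm-1),
#'   default 100.
#' @param band amide integration limits, default \code{c(1730, 1490)}.
#' @return A list with \code{cube} (scaled) and \code{usable} (logical
#'   rows x cols matrix; \code{FALSE} pixels were left unscaled).
#' @export
scaleAmide <- function(cube, targetArea = 100, band = c(1730, 1490)) {
  stopifnot(is(cube, "FtirCube"), targetArea > 0)
  wn <- cube@wavenumbers
  .checkAxisCovers(wn, min(band), max(band), "amide scaling")
  idx <- .wnWindow(wn, min(band), max(band))
  d <- dim(cube@absorbance)
  m <- .flattenPixels(cube@absorbance)
  area <- .trapzArea(m, wn, idx)
  usable <- !is.na(area) & area > 0
  fac <- ifelse(usable, targetArea / area, 1)
  m <- m * fac
  usableMat <- t(matrix(usable, nrow = d[2], ncol = d[1]))
  list(cube = initialize(cube, absorbance = .unflattenPixels(m, d[1], d[2])),
       usable = usableMat)
}

#' Subtract a piecewise-linear multi-point baseline
#'
#' The baseline is the broken line through the spectrum's values at the
#' anchor grid points (each anchor snapped to the nearest axis point),
#' evaluated between the outermost anchors and subtracted there; values
#' outside the anchored range are left unchanged. The output is exactly zero
#' at every anchor point.
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param anchors anchor wavenumbers, default \code{\link{baselineAnchors}()};
#'   every anchor must lie within the axis range.
#' @return The baseline-corrected \linkS4class{FtirCube}.
#' @export
subtractBaseline <- function(cube, anchors = baselineAnchors()) {
  stopifnot(is(cube, "FtirCube"))
  wn <- cube@wavenumbers
  out <- anchors[anchors < min(wn) - 1e-9 | anchors > max(wn) + 1e-9]
  if (length(out))
    stop("baseline anchor(s) outside the axis: ", paste(out, collapse = ", "))
  anchors <- sort(anchors, decreasing = TRUE)
  aIdx <- vapply(anchors, function(a) .wnIndex(wn, a), integer(1))
  aWn <- wn[aIdx]
  rng <- .wnWindow(wn, min(aWn), max(aWn))
  # interpolation weight matrix W: n_anchor x n_range, baseline = S_anchor %*% W
  W <- matrix(0, length(aIdx), length(rng))
  aAsc <- rev(aWn)          # ascending anchor wavenumbers
  ordAsc <- rev(seq_along(aIdx))
  seg <- findInterval(wn[rng], aAsc, rightmost.closed = TRUE)
  seg[seg < 1] <- 1; seg[seg >= length(aAsc)] <- length(aAsc) - 1
  t <- (wn[rng] - aAsc[seg]) / (aAsc[seg + 1] - aAsc[seg])
  for (j in seq_along(rng)) {
    W[ordAsc[seg[j]], j] <- W[ordAsc[seg[j]], j] + (1 - t[j])
    W[ordAsc[seg[j] + 1], j] <- W[ordAsc[seg[j] + 1], j] + t[j]
  }
  d <- dim(cube@absorbance)
  m <- .flattenPixels(cube@absorbance)
  m[, rng] <- m[, rng] - m[, aIdx, drop = FALSE] %*% W
  initialize(cube, absorbance = .unflattenPixels(m, d[1], d[2]))
}

#' Per-pixel signal-to-noise ratio map
#'
#' Noise is the sample standard deviation of the absorbances in the
#' absorption-free 2000-1900 cm-1 window (no detrending). Signal is the
#' maximum over 1730-1490 cm-1 of the spectrum after subtracting the
#' straight line joining its values at the grid points nearest 1730 and
#' 1490. Noiseless pixels receive an \code{Inf} sentinel.
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param threshold retention threshold stored in the map (default 150; 500
#'   is the convention for double clustering).
#' @param noiseBand,signalBand window limits in cm-1.
#' @return An \linkS4class{SnrMap}.
#' @export
computeSnr <- function(cube, threshold = 150, noiseBand = c(2000, 1900),
                       signalBand = c(1730, 1490)) {
  stopifnot(is(cube, "FtirCube"))
  wn <- cube@wavenumbers
  .checkAxisCovers(wn, min(noiseBand), max(noiseBand), "the SNR noise window")
  .checkAxisCovers(wn, min(signalBand), max(signalBand), "the SNR signal window")
  nIdx <- .wnWindow(wn, min(noiseBand), max(noiseBand))
  sIdx <- .wnWindow(wn, min(signalBand), max(signalBand))
  d <- dim(cube@absorbance)
  m <- .flattenPixels(cube@absorbance)
  noise <- apply(m[, nIdx, drop = FALSE], 1, stats::sd)
  sub <- m[, sIdx, drop = FALSE]
  a <- 1; b <- length(sIdx)
  w <- (wn[sIdx] - wn[sIdx[a]]) / (wn[sIdx[b]] - wn[sIdx[a]])
  line <- sub[, a] %o% (1 - w) + sub[, b] %o% w
  signal <- apply(sub - line, 1, max)
  snr <- ifelse(noise == 0, Inf, signal / noise)
  snr <- pmax(snr, 0)
  snrMat <- matrix(snr, nrow = d[2], ncol = d[1]) |> t()
  new("SnrMap", snr = snrMat, threshold = threshold)
}

#' Band ratio image
#'
#' Per-pixel ratio of the absorbance at two wavenumbers (nearest grid
#' points), e.g. A1230/A1655 highlighting phosphate-rich epithelium. Pixels
#' failing the SNR mask, no-data pixels, and zero denominators are set to
#' \code{NA}.
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param numeratorWn,denominatorWn band positions in cm-1.
#' @param snrMap optional \linkS4class{SnrMap}; masked pixels become
#'   \code{NA}.
#' @return Numeric rows x cols matrix.
#' @export
ratioImage <- function(cube, numeratorWn, denominatorWn, snrMap = NULL) {
  stopifnot(is(cube, "FtirCube"))
  wn <- cube@wavenumbers
  d <- dim(cube@absorbance)
  num <- matrix(cube@absorbance[, , .wnIndex(wn, numeratorWn)], d[1], d[2])
  den <- matrix(cube@absorbance[, , .wnIndex(wn, denominatorWn)], d[1], d[2])
  r <- num / den
  r[den == 0] <- NA
  if (!is.null(snrMap)) {
    stopifnot(is(snrMap, "SnrMap"))
    r[!snrMask(snrMap)] <- NA
  }
  r
}

#' Run the full FTIR correction chain
#'
#' Applies, in the fixed order that the method requires: water-vapor
#' subtraction, CO2 removal, amide-area scaling, piecewise-linear baseline
#' subtraction and SNR computation. The amide area equals
#' \code{targetArea} immediately after step 3 (the baseline step then
#' legitimately changes it).
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param wvRef a \linkS4class{WaterVaporReference}.
#' @param targetArea amide scaling target, default 100.
#' @param snrThreshold SNR retention threshold, default 150.
#' @param anchors baseline anchors, default \code{\link{baselineAnchors}()}.
#' @return A list with \code{cube} (corrected), \code{snr}
#'   (\linkS4class{SnrMap}), \code{usable} (scaling validity matrix) and
#'   \code{mask} (usable & SNR-retained).
#' @export
preprocessFtir <- function(cube, wvRef, targetArea = 100, snrThreshold = 150,
                           anchors = baselineAnchors()) {
  cube <- subtractWaterVapor(cube, wvRef)
  cube <- removeCO2(cube)
  sc <- scaleAmide(cube, targetArea = targetArea)
  cube <- subtractBaseline(sc$cube, anchors = anchors)
  snr <- computeSnr(cube, threshold = snrThreshold)
  list(cube = cube, snr = snr, usable = sc$usable,
       mask = sc$usable & snrMask(snr))
}
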
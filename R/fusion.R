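# Fusion of the registered FTIR cube and the elemental image into one
# pixel x feature matrix: interpolation of the spectra onto the fixed
# 1800..900 cm-1 grid (226 points), concatenation with replicated element
# channels, section-background subtraction and per-feature z-scoring.

#' The fused-analysis wavenumber grid
#'
#' @param from,to,by grid limits and spacing in cm-1; defaults give the
#'   226-point 1800..900 grid at 4 cm-1.
#' @return Numeric descending grid.
#' @export
fusionGrid <- function(from = 1800, to = 900, by = 4) {
  seq(from, to, by = -abs(by))
}

#' Interpolate FTIR spectra onto the fused-analysis grid
#'
#' Linear interpolation of every pixel spectrum onto the exact grid 1800,
#' 1796, ..., 900 cm-1 (226 points); a native 4 cm-1 axis aligned to the
#' grid is copied unchanged. Pixels are flattened row-major and their
#' coordinates kept.
#'
#' @param cube an \linkS4class{FtirCube} whose axis covers 1800-900 cm-1.
#' @param grid target grid, default \code{\link{fusionGrid}()}.
#' @return List with \code{matrix} (n_pixels x 226), \code{wavenumbers}
#'   (the grid), \code{coords} (1-based row-major pixel coordinates).
#' @export
cropInterpolateFtir <- function(cube, grid = fusionGrid()) {
  stopifnot(is(cube, "FtirCube"))
  wn <- cube@wavenumbers
  .checkAxisCovers(wn, min(grid), max(grid), "fusion interpolation")
  d <- dim(cube@absorbance)
  m <- .flattenPixels(cube@absorbance)
  asc <- order(wn)
  wnA <- wn[asc]
  seg <- findInterval(grid, wnA, rightmost.closed = TRUE)
  seg[seg < 1] <- 1; seg[seg >= length(wnA)] <- length(wnA) - 1
  t <- (grid - wnA[seg]) / (wnA[seg + 1] - wnA[seg])
  lo <- asc[seg]; hi <- asc[seg + 1]
  out <- m[, lo, drop = FALSE] * rep(1 - t, each = nrow(m)) +
         m[, hi, drop = FALSE] * rep(t, each = nrow(m))
  list(matrix = out, wavenumbers = grid, coords = .pixelCoords(d[1], d[2]))
}

#' Flatten an ElementImage to a pixels x elements matrix
#'
#' Row-major pixel order, matching \code{\link{cropInterpolateFtir}}.
#'
#' @param img an \linkS4class{ElementImage}.
#' @return List with \code{matrix}, \code{isotopes}, \code{coords}.
#' @export
flattenElementImage <- function(img) {
  stopifnot(is(img, "ElementImage"))
  d <- dim(img@counts)
  list(matrix = .flattenPixels(img@counts), isotopes = img@isotopes,
       coords = .pixelCoords(d[1], d[2]))
}

#' Concatenate FTIR and element blocks into a FusedMatrix
#'
#' Element channels are replicated \code{replicate} times (default 5) with
#' replicates adjacent, in canonical isotope order, appended after the
#' 900 cm-1 end of the FTIR block. Replication balances the 9 element
#' channels against the 226 wavenumbers, making correlation maps readable
#' and giving the elements significant weight in PCA; it is a weighting
#' device, not physics, and is configurable.
#'
#' @param ftir result of \code{\link{cropInterpolateFtir}}.
#' @param elements result of \code{flattenElementImage} (same pixel grid and
#'   ordering).
#' @param replicate replication factor, default 5.
#' @param snr optional per-pixel SNR vector (row-major), e.g. from the
#'   registered cube's \linkS4class{SnrMap}.
#' @param tissue optional per-pixel logical tissue flag (row-major).
#' @return A \linkS4class{FusedMatrix} with 226 + 9 * replicate features
#'   under the defaults.
#' @export
concatenateFeatures <- function(ftir, elements, replicate = 5, snr = NULL,
                                tissue = NULL) {
  stopifnot(replicate >= 1)
  nf <- nrow(ftir$matrix); ne <- nrow(elements$matrix)
  if (nf != ne) stop("pixel counts differ between modalities (", nf, " vs ", ne, ")")
  if (!isTRUE(all.equal(ftir$coords, elements$coords)))
    stop("pixel orderings differ between modalities")
  panel <- isotopePanel()
  ord <- order(match(elements$isotopes, panel))
  iso <- elements$isotopes[ord]
  el <- elements$matrix[, ord, drop = FALSE]
  rep_idx <- rep(seq_along(iso), each = replicate)
  elRep <- el[, rep_idx, drop = FALSE]
  values <- cbind(ftir$matrix, elRep)
  desc <- data.frame(
    kind = c(rep("wavenumber", length(ftir$wavenumbers)),
             rep("element", length(iso) * replicate)),
    wavenumber = c(ftir$wavenumbers, rep(NA_real_, length(iso) * replicate)),
    isotope = c(rep(NA_character_, length(ftir$wavenumbers)), iso[rep_idx]),
    replicate = c(rep(0L, length(ftir$wavenumbers)),
                  rep(seq_len(replicate), times = length(iso))),
    stringsAsFactors = FALSE)
  n <- nf
  if (is.null(snr)) snr <- rep(NA_real_, n)
  if (is.null(tissue)) tissue <- rep(TRUE, n)
  fused <- new("FusedMatrix", values = unname(values), descriptors = desc,
               coords = ftir$coords, snr = as.numeric(snr),
               tissue = as.logical(tissue))
  validObject(fused)
  fused
}

#' Subtract a section-specific fused background
#'
#' The mean feature vector over the pixels of a no-tissue region is
#' subtracted from every pixel, per feature, so the region mean is zero
#' afterwards.
#'
#' @param fused a \linkS4class{FusedMatrix}.
#' @param regions a \linkS4class{RegionSet} on the fused grid.
#' @return The background-subtracted \linkS4class{FusedMatrix}.
#' @export
subtractFusedBackground <- function(fused, regions) {
  stopifnot(is(fused, "FusedMatrix"), is(regions, "RegionSet"))
  rows <- max(fused@coords[, 1]); cols <- max(fused@coords[, 2])
  idx <- .regionPixelIndex(regions, rows, cols)
  lin <- (fused@coords[, 1] - 1) * cols + fused@coords[, 2]
  sel <- lin %in% idx
  if (!any(sel)) stop("region selects no fused pixels")
  # no-data pixels (e.g. rotated out of field) inside the region are skipped
  mu <- colMeans(fused@values[sel, , drop = FALSE], na.rm = TRUE)
  if (anyNA(mu)) stop("background region holds no valid pixels")
  initialize(fused, values = sweep(fused@values, 2, mu))
}

#' Standardize fused features to zero mean and unit SD
#'
#' Moments are computed over the retained pixels (default: all pixels whose
#' tissue flag is set and, when SNR is available, whose SNR passes the
#' threshold recorded on the matrix); the same affine map is applied to all
#' pixels, so quintupled element columns remain mutually identical.
#'
#' @param fused a \linkS4class{FusedMatrix}.
#' @param pixels optional logical vector selecting the pixels over which the
#'   moments are taken; default is the retained set described above.
#' @param snrThreshold SNR gate used when \code{pixels} is missing, default
#'   150.
#' @param zeroVariance "error" (default) aborts naming the offending
#'   feature; "keep" leaves zero-variance features mean-subtracted but
#'   unscaled (baseline anchor points inside the fused grid are exactly
#'   zero at every pixel, so full pipelines use "keep" and downstream maps
#'   flag those features as no-variance).
#' @return The standardized \linkS4class{FusedMatrix}.
#' @export
standardizeFused <- function(fused, pixels = NULL, snrThreshold = 150,
                             zeroVariance = c("error", "keep")) {
  stopifnot(is(fused, "FusedMatrix"))
  zeroVariance <- match.arg(zeroVariance)
  if (is.null(pixels)) pixels <- retainedPixels(fused, snrThreshold)
  if (sum(pixels) < 2) stop("need at least 2 retained pixels")
  v <- fused@values[pixels, , drop = FALSE]
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    if (zeroVariance == "error") {
      d <- fused@descriptors[zero, , drop = FALSE]
      lab <- ifelse(d$kind == "wavenumber", sprintf("wn %g", d$wavenumber),
                    sprintf("%s (replicate %d)", d$isotope, d$replicate))
      stop("zero-variance feature(s): ", paste(lab, collapse = ", "))
    }
    sdv[zero] <- 1
  }
  out <- sweep(sweep(fused@values, 2, mu), 2, sdv, "/")
  initialize(fused, values = out)
}

#' Retained-pixel selector of a fused matrix
#'
#' @param fused a \linkS4class{FusedMatrix}.
#' @param snrThreshold SNR gate (ignored for pixels without an SNR value).
#' @return Logical vector over pixels: tissue, finite values, SNR pass.
#' @export
retainedPixels <- function(fused, snrThreshold = 150) {
  stopifnot(is(fused, "FusedMatrix"))
  ok <- fused@tissue & !apply(is.na(fused@values), 1, any)
  hasSnr <- !is.na(fused@snr)
  ok[hasSnr] <- ok[hasSnr] & fused@snr[hasSnr] >= snrThreshold
  ok
}

#' Subset a fused matrix by pixels
#'
#' @param fused a \linkS4class{FusedMatrix}.
#' @param pixels logical or integer pixel selector.
#' @return The subset \linkS4class{FusedMatrix}.
#' @export
subsetPixels <- function(fused, pixels) {
  stopifnot(is(fused, "FusedMatrix"))
  initialize(fused, values = fused@values[pixels, , drop = FALSE],
             coords = fused@coords[pixels, , drop = FALSE],
             snr = fused@snr[pixels], tissue = fused@tissue[pixels])
}
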
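#' @import methods
NULL

#' FtirCube: a hyperspectral FTIR absorbance image
#'
#' Three-dimensional absorbance array (rows x cols x wavenumbers) with its
#' wavenumber axis, pixel size and (optional) mosaic tile layout. Pixels
#' flagged as no-data (e.g. mapped outside the field of view by rotation)
#' hold \code{NA} across all wavenumbers.
#'
#' @slot absorbance numeric array, rows x cols x n_wavenumbers.
#' @slot wavenumbers numeric, strictly monotonic uniform axis in cm-1.
#' @slot pixelSize numeric scalar, pixel edge in micrometers.
#' @slot tileShape integer of length 2 (tiles_y, tiles_x) or length 0 when
#'   the cube is not a mosaic.
#' @exportClass FtirCube
setClass("FtirCube",
  representation(absorbance = "array", wavenumbers = "numeric",
                 pixelSize = "numeric", tileShape = "integer"),
  prototype(pixelSize = 6.25, tileShape = integer(0)))

setValidity("FtirCube", function(object) {
  d <- dim(object@absorbance)
  if (length(d) != 3) return("absorbance must be a 3D array (rows x cols x wavenumbers)")
  if (any(d < 1)) return("all cube dimensions must be >= 1")
  if (length(object@wavenumbers) != d[3])
    return("length(wavenumbers) must equal dim(absorbance)[3]")
  msg <- .validWavenumberAxis(object@wavenumbers)
  if (!is.null(msg)) return(msg)
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    return("pixelSize must be a positive scalar")
  if (!length(object@tileShape) %in% c(0L, 2L))
    return("tileShape must be empty or length 2")
  TRUE
})

#' Construct an FtirCube
#'
#' @param absorbance rows x cols x n_wn numeric array.
#' @param wavenumbers numeric axis (cm-1), uniform and strictly monotonic.
#' @param pixelSize pixel edge in micrometers (default 6.25).
#' @param tileShape optional integer (tiles_y, tiles_x) mosaic layout.
#' @return An \linkS4class{FtirCube}.
#' @export
FtirCube <- function(absorbance, wavenumbers, pixelSize = 6.25,
                     tileShape = integer(0)) {
  new("FtirCube", absorbance = absorbance, wavenumbers = as.numeric(wavenumbers),
      pixelSize = as.numeric(pixelSize), tileShape = as.integer(tileShape))
}

#' ElementImage: a multi-element LA-ICP-MS intensity image
#'
#' @slot counts numeric array, rows x cols x n_elements (background-relative
#'   intensity, arbitrary counts).
#' @slot isotopes character labels, canonical order \code{isotopePanel()}
#'   unless an explicit subset was requested.
#' @slot pixelSize numeric scalar, micrometers.
#' @exportClass ElementImage
setClass("ElementImage",
  representation(counts = "array", isotopes = "character", pixelSize = "numeric"),
  prototype(pixelSize = 50))

setValidity("ElementImage", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3) return("counts must be a 3D array (rows x cols x elements)")
  if (length(object@isotopes) != d[3])
    return("length(isotopes) must equal dim(counts)[3]")
  if (anyDuplicated(object@isotopes)) return("duplicate isotope labels")
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    return("pixelSize must be a positive scalar")
  TRUE
})

#' Construct an ElementImage
#'
#' @param counts rows x cols x n_el numeric array.
#' @param isotopes character labels matching the third dimension.
#' @param pixelSize pixel edge in micrometers (default 50).
#' @return An \linkS4class{ElementImage}.
#' @export
ElementImage <- function(counts, isotopes = isotopePanel(), pixelSize = 50) {
  new("ElementImage", counts = counts, isotopes = as.character(isotopes),
      pixelSize = as.numeric(pixelSize))
}

#' RegionSet: rectangular regions of interest
#'
#' Rectangles are stored 0-based as (row0, col0, height, width), row 0 at the
#' top, matching the on-disk JSON convention.
#'
#' @slot rectangles integer matrix, n x 4, columns row0, col0, height, width.
#' @slot frame character, which modality's pixel grid the rectangles index
#'   ("ftir", "element" or "fused").
#' @exportClass RegionSet
setClass("RegionSet",
  representation(rectangles = "matrix", frame = "character"))

setValidity("RegionSet", function(object) {
  r <- object@rectangles
  if (ncol(r) != 4) return("rectangles must have 4 columns (row0, col0, height, width)")
  if (nrow(r) < 1) return("region set must be non-empty")
  if (any(r[, 1:2] < 0)) return("rectangle origins must be >= 0 (0-based)")
  if (any(r[, 3:4] < 1)) return("rectangle height and width must be >= 1")
  TRUE
})

#' Construct a RegionSet
#'
#' @param rectangles n x 4 matrix or data.frame of (row0, col0, height,
#'   width), 0-based pixel coordinates.
#' @param frame grid the rectangles index: "ftir", "element" or "fused".
#' @return A \linkS4class{RegionSet}.
#' @export
RegionSet <- function(rectangles, frame = "element") {
  r <- as.matrix(rectangles)
  storage.mode(r) <- "integer"
  dimnames(r) <- list(NULL, c("row0", "col0", "height", "width"))
  new("RegionSet", rectangles = r, frame = frame)
}

#' SnrMap: per-pixel signal-to-noise ratios with a retention threshold
#'
#' @slot snr numeric matrix of per-pixel SNR; \code{Inf} marks noiseless
#'   pixels.
#' @slot threshold retention threshold; a pixel is retained iff
#'   \code{snr >= threshold}.
#' @exportClass SnrMap
setClass("SnrMap", representation(snr = "matrix", threshold = "numeric"),
         prototype(threshold = 150))

setValidity("SnrMap", function(object) {
  if (length(object@threshold) != 1) return("threshold must be scalar")
  if (any(object@snr < 0, na.rm = TRUE)) return("snr must be non-negative")
  TRUE
})

#' StitchedElements: standardized elemental images assembled on a common frame
#'
#' @slot values numeric array rows x cols x n_el x n_sections after pooled
#'   per-element SD normalization.
#' @slot isotopes character labels.
#' @slot sectionIds character, one per section.
#' @slot padOffsets integer matrix n_sections x 2, 0-based (row, col) offset
#'   of each original image inside the common frame (negative when the
#'   section had to be cropped).
#' @exportClass StitchedElements
setClass("StitchedElements",
  representation(values = "array", isotopes = "character",
                 sectionIds = "character", padOffsets = "matrix"))

setValidity("StitchedElements", function(object) {
  d <- dim(object@values)
  if (length(d) != 4) return("values must be rows x cols x elements x sections")
  if (length(object@isotopes) != d[3]) return("isotope labels must match dim 3")
  if (length(object@sectionIds) != d[4]) return("sectionIds must match dim 4")
  if (nrow(object@padOffsets) != d[4]) return("padOffsets must have one row per section")
  TRUE
})

#' FusedMatrix: concatenated per-pixel FTIR + element feature table
#'
#' Rows are pixels of the co-registered low-resolution grid (row-major
#' order); columns are wavenumber features followed by replicated element
#' features. Feature provenance is kept in \code{descriptors}.
#'
#' @slot values numeric matrix, n_pixels x n_features.
#' @slot descriptors data.frame with columns \code{kind} ("wavenumber" or
#'   "element"), \code{wavenumber}, \code{isotope}, \code{replicate}
#'   (1..replication for elements, 0 for wavenumbers).
#' @slot coords integer matrix n_pixels x 2, 1-based (row, col) on the fused
#'   grid.
#' @slot snr numeric per-pixel SNR carried from the registered FTIR cube.
#' @slot tissue logical per-pixel tissue flag from the elemental modality.
#' @exportClass FusedMatrix
setClass("FusedMatrix",
  representation(values = "matrix", descriptors = "data.frame",
                 coords = "matrix", snr = "numeric", tissue = "logical"))

setValidity("FusedMatrix", function(object) {
  if (nrow(object@descriptors) != ncol(object@values))
    return("descriptor count must equal value columns")
  if (nrow(object@coords) != nrow(object@values))
    return("coords must have one row per pixel")
  if (length(object@snr) != nrow(object@values))
    return("snr must have one entry per pixel")
  if (length(object@tissue) != nrow(object@values))
    return("tissue flag must have one entry per pixel")
  need <- c("kind", "wavenumber", "isotope", "replicate")
  if (!all(need %in% names(object@descriptors)))
    return("descriptors must have kind, wavenumber, isotope, replicate columns")
  TRUE
})

#' CorrelationMap: feature-by-feature Pearson correlation matrix
#'
#' @slot matrix symmetric correlation matrix; rows/columns of zero-variance
#'   features are \code{NA} and flagged in \code{zeroVariance}.
#' @slot descriptors feature descriptor data.frame (as in
#'   \linkS4class{FusedMatrix}).
#' @slot zeroVariance logical flag per feature.
#' @exportClass CorrelationMap
setClass("CorrelationMap",
  representation(matrix = "matrix", descriptors = "data.frame",
                 zeroVariance = "logical"))

#' PcaModel: principal component decomposition of a pixel x feature matrix
#'
#' @slot loadings n_features x n_pc orthonormal matrix.
#' @slot scores n_pixels x n_pc score matrix.
#' @slot varianceFraction fraction of total (centered or raw) sum of squares
#'   per component, descending.
#' @slot centered whether the feature means were subtracted before the
#'   decomposition; when \code{FALSE} the first component absorbs the mean
#'   direction.
#' @slot center the feature mean vector used (zeros when uncentered).
#' @exportClass PcaModel
setClass("PcaModel",
  representation(loadings = "matrix", scores = "matrix",
                 varianceFraction = "numeric", centered = "logical",
                 center = "numeric"))

#' DoubleClusterResult: joint pixel / feature ordering of a fused matrix
#'
#' @slot spectrumOrder permutation of retained pixel indices (dendrogram leaf
#'   order).
#' @slot featureAssignment K-means cluster label per feature.
#' @slot featureOrder permutation of features (cluster blocks in label order,
#'   original order within blocks).
#' @slot K number of feature clusters.
#' @slot sortedMatrix the standardized matrix re-ordered on both axes.
#' @slot sortedSpectrum cluster-ordered mean feature vector prior to
#'   standardization.
#' @slot descriptors feature descriptors in sorted order.
#' @exportClass DoubleClusterResult
setClass("DoubleClusterResult",
  representation(spectrumOrder = "integer", featureAssignment = "integer",
                 featureOrder = "integer", K = "integer",
                 sortedMatrix = "matrix", sortedSpectrum = "numeric",
                 descriptors = "data.frame"))

#' SyntheticScene: ground-truth description of a paired FTIR / LA-ICP-MS scene
#'
#' Holds the class map (0 background, 1 stroma, 2 epithelium, 3 duct lumen)
#' on the high-resolution FTIR grid, per-class endmember spectra and element
#' abundances, every corrupting field (thickness, baseline drift, water-vapor
#' coefficient), the true rotation offset between the two frames, planted
#' cross-modal and within-FTIR correlations with their latent fields, and the
#' seed. Rendering is a pure function of the scene.
#'
#' @slot classMap integer matrix on the FTIR grid.
#' @slot wavenumbers FTIR axis.
#' @slot classSpectra 4 x n_wn matrix (background, stroma, epithelium, lumen).
#' @slot classElements 4 x n_el matrix of mean abundances.
#' @slot isotopes element labels.
#' @slot crossCorr data.frame(isotope, wavenumber, rho) planted cross-modal
#'   correlations.
#' @slot ftirCorr data.frame(wavenumber1, wavenumber2, rho) planted
#'   within-FTIR correlations.
#' @slot thicknessField multiplicative per-pixel section-thickness factor.
#' @slot wvCoeffField per-pixel water-vapor contamination amplitude.
#' @slot theta true rotation offset (degrees) between FTIR and element frames.
#' @slot laShape target elemental grid (rows, cols).
#' @slot noise list of noise/drift parameters (ftirSd, elementSd,
#'   elementOffsets, driftAmplitude, co2Amplitude, bandAmplitude).
#' @slot latents list of latent fields realizing the planted correlations.
#' @slot seed integer master seed.
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(classMap = "matrix", wavenumbers = "numeric",
                 classSpectra = "matrix", classElements = "matrix",
                 isotopes = "character", crossCorr = "data.frame",
                 ftirCorr = "data.frame", thicknessField = "matrix",
                 wvCoeffField = "matrix", theta = "numeric",
                 laShape = "integer", noise = "list", latents = "list",
                 seed = "integer"))

setValidity("SyntheticScene", function(object) {
  if (nrow(object@classSpectra) != 4) return("classSpectra must have 4 rows")
  if (ncol(object@classSpectra) != length(object@wavenumbers))
    return("classSpectra columns must match axis length")
  if (nrow(object@classElements) != 4) return("classElements must have 4 rows")
  if (ncol(object@classElements) != length(object@isotopes))
    return("classElements columns must match isotopes")
  if (nrow(object@crossCorr) && any(abs(object@crossCorr$rho) > 1))
    return("planted rho must lie in [-1, 1]")
  if (!identical(dim(object@classMap), dim(object@thicknessField)))
    return("thicknessField must match classMap")
  TRUE
})
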
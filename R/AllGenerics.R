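# Accessor generics + show methods. Slots are never touched outside the
# package; user code goes through these.

#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))
#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("tileShape", function(x) standardGeneric("tileShape"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("isotopes", function(x) standardGeneric("isotopes"))
#' @rdname accessors
#' @export
setGeneric("fusedValues", function(x) standardGeneric("fusedValues"))
#' @rdname accessors
#' @export
setGeneric("featureDescriptors", function(x) standardGeneric("featureDescriptors"))
#' @rdname accessors
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))
#' @rdname accessors
#' @export
setGeneric("snrValues", function(x) standardGeneric("snrValues"))
#' @rdname accessors
#' @export
setGeneric("snrMask", function(x) standardGeneric("snrMask"))
#' @rdname accessors
#' @export
setGeneric("tissuePixels", function(x) standardGeneric("tissuePixels"))
#' @rdname accessors
#' @export
setGeneric("regionRectangles", function(x) standardGeneric("regionRectangles"))
#' @rdname accessors
#' @export
setGeneric("classMap", function(x) standardGeneric("classMap"))
#' @rdname accessors
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

#' Accessors for specfuse classes
#'
#' @name accessors
#' @return The corresponding slot content.
NULL

#' @rdname accessors
setMethod("absorbance", "FtirCube", function(x) x@absorbance)
#' @rdname accessors
setMethod("wavenumbers", "FtirCube", function(x) x@wavenumbers)
#' @rdname accessors
setMethod("pixelSize", "FtirCube", function(x) x@pixelSize)
#' @rdname accessors
setMethod("tileShape", "FtirCube", function(x) x@tileShape)
#' @rdname accessors
setMethod("counts", "ElementImage", function(x) x@counts)
#' @rdname accessors
setMethod("isotopes", "ElementImage", function(x) x@isotopes)
#' @rdname accessors
setMethod("pixelSize", "ElementImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("isotopes", "StitchedElements", function(x) x@isotopes)
#' @rdname accessors
setMethod("fusedValues", "FusedMatrix", function(x) x@values)
#' @rdname accessors
setMethod("featureDescriptors", "FusedMatrix", function(x) x@descriptors)
#' @rdname accessors
setMethod("pixelCoords", "FusedMatrix", function(x) x@coords)
#' @rdname accessors
setMethod("snrValues", "FusedMatrix", function(x) x@snr)
#' @rdname accessors
setMethod("tissuePixels", "FusedMatrix", function(x) x@tissue)
#' @rdname accessors
setMethod("snrValues", "SnrMap", function(x) x@snr)
#' @rdname accessors
setMethod("snrMask", "SnrMap", function(x) x@snr >= x@threshold)
#' @rdname accessors
setMethod("regionRectangles", "RegionSet", function(x) x@rectangles)
#' @rdname accessors
setMethod("classMap", "SyntheticScene", function(x) x@classMap)
#' @rdname accessors
setMethod("wavenumbers", "SyntheticScene", function(x) x@wavenumbers)
#' @rdname accessors
setMethod("isotopes", "SyntheticScene", function(x) x@isotopes)
#' @rdname accessors
setMethod("loadings", "PcaModel", function(x) x@loadings)
#' @rdname accessors
setMethod("scores", "PcaModel", function(x) x@scores)
#' @rdname accessors
setMethod("varianceFraction", "PcaModel", function(x) x@varianceFraction)

#' Dimensions of image containers
#'
#' @param x an \linkS4class{FtirCube} or \linkS4class{ElementImage}.
#' @return Integer dimensions of the underlying array.
#' @export
setMethod("dim", "FtirCube", function(x) dim(x@absorbance))
#' @rdname dim-FtirCube-method
#' @export
setMethod("dim", "ElementImage", function(x) dim(x@counts))

#' Number of tiles in a mosaic cube
#'
#' @param x an \linkS4class{FtirCube} with tile layout metadata.
#' @return Number of tiles (tiles_y * tiles_x), or \code{NA} if the cube is
#'   not a mosaic.
#' @export
tileCount <- function(x) {
  stopifnot(is(x, "FtirCube"))
  if (length(x@tileShape) != 2) return(NA_integer_)
  as.integer(prod(x@tileShape))
}

setMethod("show", "FtirCube", function(object) {
  d <- dim(object@absorbance)
  wn <- object@wavenumbers
  cat(sprintf("FtirCube: %d x %d pixels, %d wavenumbers (%g to %g cm-1, step %g)\n",
              d[1], d[2], d[3], wn[1], wn[length(wn)], wn[2] - wn[1]))
  cat(sprintf("  pixel size %g um", object@pixelSize))
  if (length(object@tileShape) == 2)
    cat(sprintf("; mosaic %d x %d tiles", object@tileShape[1], object@tileShape[2]))
  nd <- sum(is.na(object@absorbance[, , 1]))
  if (nd > 0) cat(sprintf("; %d no-data pixels", nd))
  cat("\n")
})

setMethod("show", "ElementImage", function(object) {
  d <- dim(object@counts)
  cat(sprintf("ElementImage: %d x %d pixels, %d elements (%s)\n",
              d[1], d[2], d[3], paste(object@isotopes, collapse = ", ")))
  cat(sprintf("  pixel size %g um\n", object@pixelSize))
})

setMethod("show", "FusedMatrix", function(object) {
  nw <- sum(object@descriptors$kind == "wavenumber")
  ne <- sum(object@descriptors$kind == "element")
  cat(sprintf("FusedMatrix: %d pixels x %d features (%d wavenumbers + %d element columns)\n",
              nrow(object@values), ncol(object@values), nw, ne))
  cat(sprintf("  tissue pixels: %d; SNR available: %s\n",
              sum(object@tissue), !all(is.na(object@snr))))
})

setMethod("show", "SnrMap", function(object) {
  cat(sprintf("SnrMap: %d x %d, threshold %g, retained %d/%d pixels\n",
              nrow(object@snr), ncol(object@snr), object@threshold,
              sum(object@snr >= object@threshold, na.rm = TRUE),
              length(object@snr)))
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@classMap)
  cat(sprintf("SyntheticScene: FTIR grid %d x %d, element grid %d x %d, theta %g deg, seed %d\n",
              d[1], d[2], object@laShape[1], object@laShape[2],
              object@theta, object@seed))
  cat(sprintf("  tissue fraction %.2f; %d planted cross-modal, %d within-FTIR correlations\n",
              mean(object@classMap > 0), nrow(object@crossCorr), nrow(object@ftirCorr)))
})

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d features x %d components (%scentered)\n",
              nrow(object@loadings), ncol(object@loadings),
              if (object@centered) "" else "un"))
  cat("  variance fractions:",
      paste(sprintf("%.3f", utils::head(object@varianceFraction, 6)), collapse = " "),
      if (length(object@varianceFraction) > 6) "..." else "", "\n")
})

setMethod("show", "CorrelationMap", function(object) {
  cat(sprintf("CorrelationMap: %d x %d features, %d zero-variance flagged\n",
              nrow(object@matrix), ncol(object@matrix), sum(object@zeroVariance)))
})

setMethod("show", "DoubleClusterResult", function(object) {
  cat(sprintf("DoubleClusterResult: %d pixels ordered by HCA, %d features in %d K-means clusters\n",
              length(object@spectrumOrder), length(object@featureAssignment),
              object@K))
})
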
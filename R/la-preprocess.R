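# Elemental-image processing: background subtraction from operator-drawn
# no-tissue rectangles, per-element standardization, zero-padding onto a
# common 180 x 180 frame, pooled stitching, and the positivity tissue mask.

#' Subtract the mean background spectrum from an elemental image
#'
#' All pixels inside the region rectangles (areas without tissue) are
#' averaged per element and the mean is subtracted from every pixel, so the
#' region mean of the output is zero for every element.
#'
#' @param img an \linkS4class{ElementImage}.
#' @param regions a \linkS4class{RegionSet} on the element grid.
#' @return The background-subtracted \linkS4class{ElementImage}.
#' @export
subtractLaBackground <- function(img, regions) {
  stopifnot(is(img, "ElementImage"), is(regions, "RegionSet"))
  d <- dim(img@counts)
  mask <- .regionMask(regions, d[1], d[2])
  if (!any(mask)) stop("region set selects no pixels")
  a <- img@counts
  for (e in seq_len(d[3])) {
    plane <- a[, , e]
    a[, , e] <- plane - mean(plane[mask])
  }
  initialize(img, counts = a)
}

#' Standardize each element channel to zero mean and unit SD
#'
#' Classic z-scoring over all pixels of the image, per element; makes the
#' widely differing intensity scales of the elements comparable. On typical
#' sections (tissue covering less than half of the frame) the no-tissue
#' background maps to negative values and tissue to positive values. The
#' operation is idempotent.
#'
#' @param img an \linkS4class{ElementImage}.
#' @return The standardized \linkS4class{ElementImage}.
#' @export
standardizeElementImage <- function(img) {
  stopifnot(is(img, "ElementImage"))
  a <- img@counts
  for (e in seq_len(dim(a)[3])) {
    plane <- a[, , e]
    s <- stats::sd(as.vector(plane))
    if (!is.finite(s) || s == 0)
      stop("element ", img@isotopes[e], " has zero standard deviation")
    a[, , e] <- (plane - mean(plane)) / s
  }
  initialize(img, counts = a)
}

#' Pad (or crop) an elemental image onto a common frame
#'
#' The original content is centered in the frame; an odd remainder goes to
#' the bottom/right. Dimensions exceeding the frame are center-cropped
#' (offsets are then negative).
#'
#' @param img an \linkS4class{ElementImage}.
#' @param frame target (rows, cols), default \code{c(180, 180)}.
#' @param fill pad value, default 0.
#' @return A list with \code{image} (padded/cropped
#'   \linkS4class{ElementImage}) and \code{offsets} (0-based (row, col) of
#'   the original origin inside the frame).
#' @export
padToFrame <- function(img, frame = c(180, 180), fill = 0) {
  stopifnot(is(img, "ElementImage"))
  d <- dim(img@counts)
  frame <- as.integer(frame)
  # centered; the odd remainder pads (or crops) on the bottom/right side
  off <- ifelse(frame >= d[1:2], floor((frame - d[1:2]) / 2),
                -floor((d[1:2] - frame) / 2))
  a <- array(fill, dim = c(frame, d[3]))
  srcR <- seq_len(d[1]) + off[1]
  srcC <- seq_len(d[2]) + off[2]
  keepR <- srcR >= 1 & srcR <= frame[1]
  keepC <- srcC >= 1 & srcC <= frame[2]
  a[srcR[keepR], srcC[keepC], ] <- img@counts[keepR, keepC, , drop = FALSE]
  list(image = initialize(img, counts = a), offsets = off)
}

#' Assemble padded sections into one stitched, renormalized matrix
#'
#' All sections must share the frame and isotope panel. After assembly, each
#' element channel is divided by its standard deviation pooled over all
#' pixels of all sections, so between-section abundance comparisons are on a
#' common scale.
#'
#' @param padded list of results from \code{\link{padToFrame}} (or of
#'   \linkS4class{ElementImage}s already on the frame).
#' @param sectionIds optional character ids, default \code{"section_i"}.
#' @param tissueOnly if \code{TRUE}, the pooled SD is computed over
#'   tissue-candidate (positive 13C) pixels only; default \code{FALSE} uses
#'   all pixels.
#' @return A \linkS4class{StitchedElements}.
#' @export
stitchSections <- function(padded, sectionIds = NULL, tissueOnly = FALSE) {
  imgs <- lapply(padded, function(p) if (is(p, "ElementImage")) p else p$image)
  offs <- t(vapply(padded, function(p) {
    if (is(p, "ElementImage")) c(0L, 0L) else as.integer(p$offsets)
  }, integer(2)))
  n <- length(imgs)
  stopifnot(n >= 1)
  iso <- imgs[[1]]@isotopes
  d <- dim(imgs[[1]]@counts)
  for (im in imgs) {
    if (!identical(im@isotopes, iso)) stop("isotope panels differ between sections")
    if (!identical(dim(im@counts), d)) stop("section frames differ; pad first")
  }
  v <- array(0, dim = c(d[1], d[2], d[3], n))
  for (i in seq_len(n)) v[, , , i] <- imgs[[i]]@counts
  cIdx <- match("13C", iso)
  for (e in seq_len(d[3])) {
    vals <- v[, , e, ]
    if (tissueOnly) {
      if (is.na(cIdx)) stop("tissueOnly pooling requires the 13C channel")
      vals <- vals[v[, , cIdx, ] > 0]
    }
    s <- stats::sd(as.vector(vals))
    if (!is.finite(s) || s == 0)
      stop("element ", iso[e], " has zero pooled standard deviation")
    v[, , e, ] <- v[, , e, ] / s
  }
  if (is.null(sectionIds)) sectionIds <- paste0("section_", seq_len(n))
  new("StitchedElements", values = v, isotopes = iso,
      sectionIds = as.character(sectionIds), padOffsets = offs)
}

#' Total number of spectra (pixels) in a stitched matrix
#'
#' @param x a \linkS4class{StitchedElements}.
#' @return Number of pixels across all sections.
#' @export
stitchedPixelCount <- function(x) {
  stopifnot(is(x, "StitchedElements"))
  d <- dim(x@values)
  as.integer(d[1] * d[2] * d[4])
}

#' Tissue / no-tissue mask from element positivity
#'
#' After background subtraction and standardization, no-tissue areas carry
#' negative values; the default rule retains pixels where both 13C and 64Zn
#' are positive. "or" retains pixels where either is positive; "13C" uses
#' carbon alone.
#'
#' @param x an \linkS4class{ElementImage} or \linkS4class{StitchedElements}.
#' @param rule "and" (default), "or" or "13C".
#' @return Logical mask: rows x cols for an image, rows x cols x sections
#'   for a stitched matrix.
#' @export
tissueMask <- function(x, rule = c("and", "or", "13C")) {
  rule <- match.arg(rule)
  iso <- if (is(x, "ElementImage")) x@isotopes else x@isotopes
  need <- if (rule == "13C") "13C" else c("13C", "64Zn")
  miss <- setdiff(need, iso)
  if (length(miss)) stop("mask rule needs absent element(s): ",
                         paste(miss, collapse = ", "))
  getChan <- function(lab) {
    i <- match(lab, iso)
    if (is(x, "ElementImage")) x@counts[, , i] else x@values[, , i, ]
  }
  c13 <- getChan("13C")
  switch(rule,
         "13C" = c13 > 0,
         "and" = c13 > 0 & getChan("64Zn") > 0,
         "or"  = c13 > 0 | getChan("64Zn") > 0)
}
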
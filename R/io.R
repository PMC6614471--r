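# On-disk formats: ENVI header+binary for FTIR cubes, per-isotope headerless
# CSV grids for element maps, JSON for region sets, and an R-native
# serialized container (.rds) for lossless round-trips of any pipeline
# object. All coordinates on disk are 0-based (row, col), row 0 at the top.

#' Read an FTIR absorbance cube
#'
#' @param path file path; for ENVI the flat binary (a sibling \code{.hdr}
#'   header must exist), for the native format an \code{.rds} container
#'   written by \code{\link{writeFtirCube}}.
#' @param format "envi" or "native".
#' @return An \linkS4class{FtirCube} with a validated wavenumber axis.
#' @export
readFtirCube <- function(path, format = c("envi", "native")) {
  format <- match.arg(format)
  if (format == "native") {
    cube <- readRDS(path)
    if (!is(cube, "FtirCube")) stop("native container does not hold an FtirCube")
    validObject(cube)
    return(cube)
  }
  raw <- .readEnviCube(path)
  cube <- FtirCube(raw$absorbance, raw$wavenumbers)
  validObject(cube)
  cube
}

#' Write an FTIR absorbance cube
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param path output path (ENVI writes \code{path} + \code{path.hdr}).
#' @param format "envi" or "native".
#' @return The path, invisibly.
#' @export
writeFtirCube <- function(cube, path, format = c("envi", "native")) {
  stopifnot(is(cube, "FtirCube"))
  format <- match.arg(format)
  if (format == "native") saveRDS(cube, path) else .writeEnviCube(cube, path)
  invisible(path)
}

#' Read per-isotope CSV element maps into an ElementImage
#'
#' Each CSV is a plain rectangular numeric grid with no header row; the
#' isotope is identified by the filename stem (e.g. \code{64Zn.csv}).
#' Regardless of the input order, channels are stacked in the canonical
#' panel order unless \code{subset = TRUE}.
#'
#' @param paths character vector of CSV paths (or a directory containing
#'   them).
#' @param pixelSize pixel edge in micrometers.
#' @param subset allow fewer than the canonical nine isotopes; labels are
#'   preserved (sorted into canonical relative order).
#' @return An \linkS4class{ElementImage}.
#' @export
readElementMaps <- function(paths, pixelSize = 50, subset = FALSE) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
  stems <- sub("\\.csv$", "", basename(paths))
  panel <- isotopePanel()
  unknown <- setdiff(stems, panel)
  if (length(unknown))
    stop("unknown isotope label(s): ", paste(unknown, collapse = ", "))
  if (!subset && !setequal(stems, panel))
    stop("expected all 9 canonical isotopes; missing: ",
         paste(setdiff(panel, stems), collapse = ", "),
         " (use subset = TRUE for a partial panel)")
  keep <- panel[panel %in% stems]
  paths <- paths[match(keep, stems)]
  grids <- lapply(paths, function(p) {
    as.matrix(utils::read.csv(p, header = FALSE))
  })
  shapes <- vapply(grids, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("element map grids differ in shape")
  a <- array(0, dim = c(shapes[1, 1], shapes[2, 1], length(keep)))
  for (i in seq_along(grids)) a[, , i] <- grids[[i]]
  dimnames(a) <- NULL
  img <- ElementImage(a, isotopes = keep, pixelSize = pixelSize)
  validObject(img)
  img
}

#' Write an ElementImage as per-isotope CSV grids
#'
#' @param img an \linkS4class{ElementImage}.
#' @param dir output directory (created if absent); one
#'   \code{<isotope>.csv} per channel, headerless.
#' @return The directory, invisibly.
#' @export
writeElementMaps <- function(img, dir) {
  stopifnot(is(img, "ElementImage"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(img@isotopes)) {
    utils::write.table(img@counts[, , i],
                       file.path(dir, paste0(img@isotopes[i], ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read / write a region set as JSON
#'
#' Rectangles are serialized 0-based as objects with \code{row0},
#' \code{col0}, \code{height}, \code{width}, plus a \code{frame} field naming
#' the pixel grid they index.
#'
#' @param path JSON file path.
#' @return \code{readRegions}: a \linkS4class{RegionSet}.
#' @export
readRegions <- function(path) {
  obj <- jsonlite::fromJSON(path)
  r <- as.matrix(obj$rectangles[, c("row0", "col0", "height", "width")])
  rs <- RegionSet(r, frame = if (is.null(obj$frame)) "element" else obj$frame)
  validObject(rs)
  rs
}

#' @rdname readRegions
#' @param regions a \linkS4class{RegionSet}.
#' @export
writeRegions <- function(regions, path) {
  stopifnot(is(regions, "RegionSet"))
  obj <- list(frame = regions@frame,
              rectangles = as.data.frame(regions@rectangles))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Lossless native container for fused matrices and other pipeline objects
#'
#' Values, feature descriptors, pixel coordinates and masks round-trip
#' bit-exactly through R serialization.
#'
#' @param fused a \linkS4class{FusedMatrix}.
#' @param path \code{.rds} path.
#' @return \code{readFused}: the restored \linkS4class{FusedMatrix}.
#' @export
writeFused <- function(fused, path) {
  stopifnot(is(fused, "FusedMatrix"))
  saveRDS(fused, path)
  invisible(path)
}

#' @rdname writeFused
#' @export
readFused <- function(path) {
  fused <- readRDS(path)
  if (!is(fused, "FusedMatrix")) stop("container does not hold a FusedMatrix")
  validObject(fused)
  fused
}

#' Export a fused matrix as CSV with a descriptor header row
#'
#' @param fused a \linkS4class{FusedMatrix}.
#' @param path output CSV.
#' @return The path, invisibly.
#' @export
writeFusedCsv <- function(fused, path) {
  stopifnot(is(fused, "FusedMatrix"))
  d <- fused@descriptors
  hdr <- ifelse(d$kind == "wavenumber",
                sprintf("wn_%g", d$wavenumber),
                sprintf("%s_r%d", d$isotope, d$replicate))
  m <- fused@values
  colnames(m) <- hdr
  utils::write.csv(cbind(as.data.frame(fused@coords), as.data.frame(m)),
                   path, row.names = FALSE)
  invisible(path)
}

## 1-based linear pixel indices (row-major order over a rows x cols grid)
## covered by a 0-based RegionSet
.regionPixelIndex <- function(regions, rows, cols) {
  r <- regions@rectangles
  if (any(r[, 1] + r[, 3] > rows) || any(r[, 2] + r[, 4] > cols))
    stop("region rectangle extends beyond image bounds")
  idx <- unlist(lapply(seq_len(nrow(r)), function(i) {
    rr <- (r[i, 1] + 1):(r[i, 1] + r[i, 3])
    cc <- (r[i, 2] + 1):(r[i, 2] + r[i, 4])
    as.vector(outer((rr - 1) * cols, cc, "+"))
  }))
  sort(unique(idx))
}

## same but as a logical rows x cols matrix
.regionMask <- function(regions, rows, cols) {
  m <- matrix(FALSE, rows, cols)
  r <- regions@rectangles
  if (any(r[, 1] + r[, 3] > rows) || any(r[, 2] + r[, 4] > cols))
    stop("region rectangle extends beyond image bounds")
  for (i in seq_len(nrow(r))) {
    m[(r[i, 1] + 1):(r[i, 1] + r[i, 3]),
      (r[i, 2] + 1):(r[i, 2] + r[i, 4])] <- TRUE
  }
  m
}
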
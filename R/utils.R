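# Shared wavenumber-axis helpers. The axis is stored exactly as acquired
# (typically descending, 4000 -> 700 cm-1 in 4 cm-1 steps); all band and
# anchor lookups snap to the nearest grid point, never interpolate sub-grid.

#' Canonical LA-ICP-MS isotope panel
#'
#' The nine isotopes recorded by the elemental modality, in the canonical
#' order enforced throughout the package.
#'
#' @return Character vector of isotope labels.
#' @export
isotopePanel <- function() {
  c("13C", "31P", "34S", "52Cr", "55Mn", "56Fe", "58Ni", "63Cu", "64Zn")
}

## nearest grid index for a target wavenumber
.wnIndex <- function(wn, target) which.min(abs(wn - target))

## indices spanning the band [lo, hi], endpoints snapped to nearest grid
## points; returned in axis (storage) order
.wnWindow <- function(wn, lo, hi) {
  i1 <- .wnIndex(wn, lo)
  i2 <- .wnIndex(wn, hi)
  seq(min(i1, i2), max(i1, i2))
}

.checkAxisCovers <- function(wn, lo, hi, what = "operation") {
  if (min(wn) > lo + 1e-9 || max(wn) < hi - 1e-9) {
    stop(sprintf("wavenumber axis [%g, %g] does not cover %g-%g cm-1 required for %s",
                 min(wn), max(wn), lo, hi, what))
  }
  invisible(TRUE)
}

## validate a wavenumber axis: strictly monotonic, uniform spacing
.validWavenumberAxis <- function(wn) {
  if (length(wn) < 1) return("wavenumber axis is empty")
  if (length(wn) == 1) return(NULL)   # single-plane cube
  d <- diff(wn)
  if (!(all(d > 0) || all(d < 0))) return("wavenumber axis must be strictly monotonic")
  if (max(abs(d - d[1])) > 1e-9) return("wavenumber axis spacing must be uniform (within 1e-9)")
  NULL
}

## trapezoidal band area of row-wise spectra over a wavenumber window,
## positive orientation regardless of axis direction.
## mat: n_spectra x n_wn matrix, wn: axis, idx: window indices (axis order)
.trapzArea <- function(mat, wn, idx) {
  w <- abs(diff(wn[idx]))
  sub <- mat[, idx, drop = FALSE]
  n <- length(idx)
  as.vector((sub[, -n, drop = FALSE] + sub[, -1, drop = FALSE]) %*% (w / 2))
}

## band area after subtracting the straight line joining the window's two
## endpoint absorbances (the trapezoid of that line is exact, so the
## correction reduces to the endpoint mean times the band width)
.localLineArea <- function(mat, wn, idx) {
  n <- length(idx)
  width <- abs(wn[idx[n]] - wn[idx[1]])
  raw <- .trapzArea(mat, wn, idx)
  raw - (mat[, idx[1]] + mat[, idx[n]]) / 2 * width
}

## flatten a rows x cols x k array to (rows*cols) x k matrix, row-major
## pixel order (pixel index = (row-1)*cols + col), and back
.flattenPixels <- function(a) {
  d <- dim(a)
  m <- matrix(aperm(a, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
  m
}

.unflattenPixels <- function(m, rows, cols) {
  a <- array(m, dim = c(cols, rows, ncol(m)))
  aperm(a, c(2L, 1L, 3L))
}

## row-major pixel coordinates (row, col), 1-based, matching .flattenPixels
.pixelCoords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

## seeded evaluation that restores the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
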
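# Co-registration of the FTIR cube onto the elemental grid: rigid rotation
# about the image center (bilinear), non-overlapping pixel binning, and
# per-wavenumber Fourier-domain crop resampling. All three stages are
# linear in the absorbance values for fixed geometry.

## inverse-mapped source coordinates for a rotation by theta degrees about
## the image center; content is moved forward by R(theta)
.rotationSourceCoords <- function(nr, nc, theta) {
  th <- theta * pi / 180
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  dr <- rep(seq_len(nr), times = nc) - cy
  dc <- rep(seq_len(nc), each = nr) - cx
  list(sr = cy + cos(th) * dr + sin(th) * dc,
       sc = cx - sin(th) * dr + cos(th) * dc)
}

#' Rotate a cube about its center
#'
#' Applies the rotation matrix [cos(theta) -sin(theta); sin(theta)
#' cos(theta)] to the pixel coordinates and interpolates bilinearly on the
#' inverse-mapped source positions. Output shape equals input shape; pixels
#' mapping outside the source are flagged \code{NA}. \code{theta = 0} is the
#' identity.
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param theta rotation in degrees, \code{abs(theta) < 90}.
#' @return The rotated \linkS4class{FtirCube}.
#' @export
rotateCube <- function(cube, theta) {
  stopifnot(is(cube, "FtirCube"), abs(theta) < 90)
  if (theta == 0) return(cube)
  d <- dim(cube@absorbance)
  nr <- d[1]; nc <- d[2]
  co <- .rotationSourceCoords(nr, nc, theta)
  sr <- co$sr; sc <- co$sc
  valid <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  r0 <- pmin(pmax(floor(sr), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(sc), 1), nc); c1 <- pmin(c0 + 1, nc)
  fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc - c0, 0), 1)
  M <- matrix(cube@absorbance, nr * nc, d[3])      # column-major pixel index
  ix <- function(r, c) (c - 1) * nr + r
  out <- (1 - fr) * (1 - fc) * M[ix(r0, c0), , drop = FALSE] +
         (1 - fr) * fc       * M[ix(r0, c1), , drop = FALSE] +
         fr       * (1 - fc) * M[ix(r1, c0), , drop = FALSE] +
         fr       * fc       * M[ix(r1, c1), , drop = FALSE]
  out[!valid, ] <- NA
  initialize(cube, absorbance = array(out, dim = d))
}

## nearest-neighbor rotation of an integer-labeled matrix; outside -> fill
.rotateMatrixNearest <- function(m, theta, fill = 0L) {
  if (theta == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  co <- .rotationSourceCoords(nr, nc, theta)
  sr <- round(co$sr); sc <- round(co$sc)
  valid <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out <- rep(fill, nr * nc)
  out[valid] <- m[cbind(sr[valid], sc[valid])]
  matrix(out, nr, nc)
}

#' Bin a cube by non-overlapping block averaging
#'
#' Each output pixel is the mean of a \code{factor x factor} block; trailing
#' rows/columns not filling a complete block are dropped. For i.i.d. pixel
#' noise the binned noise SD scales as 1/factor, which is what makes the
#' low-resolution spectra so clean.
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param factor integer >= 1.
#' @return The binned \linkS4class{FtirCube} (pixel size multiplied by
#'   \code{factor}).
#' @export
binCube <- function(cube, factor) {
  stopifnot(is(cube, "FtirCube"), factor >= 1, factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1) return(cube)
  d <- dim(cube@absorbance)
  nrB <- d[1] %/% factor; ncB <- d[2] %/% factor
  if (nrB < 1 || ncB < 1) stop("bin factor larger than the image")
  a <- cube@absorbance[seq_len(nrB * factor), seq_len(ncB * factor), , drop = FALSE]
  dim(a) <- c(factor, nrB, factor, ncB, d[3])
  b <- colMeans(a, dims = 1)                      # (nrB, factor, ncB, nwn)
  b <- colMeans(aperm(b, c(2, 1, 3, 4)), dims = 1) # (nrB, ncB, nwn)
  initialize(cube, absorbance = b, pixelSize = cube@pixelSize * factor)
}

# circular shifts moving the zero-frequency bin to the array center
# (left-roll by ceiling(d/2)) and back to index 1 (left-roll by floor(d/2))
.fftshift2 <- function(x) {
  d <- dim(x)
  s <- ceiling(d / 2)
  x[c(seq(s[1] + 1, d[1]), seq_len(s[1])),
    c(seq(s[2] + 1, d[2]), seq_len(s[2])), drop = FALSE]
}

.ifftshift2 <- function(x) {
  d <- dim(x)
  s <- floor(d / 2)
  x[c(seq(s[1] + 1, d[1]), seq_len(s[1])),
    c(seq(s[2] + 1, d[2]), seq_len(s[2])), drop = FALSE]
}

#' Downsample a 2D plane by Fourier-spectrum cropping
#'
#' Computes the 2D DFT, keeps the centered low-frequency block of the target
#' size (for even targets the extra Nyquist line is taken from the
#' negative-frequency side), inverse-transforms, forces the result real and
#' rescales by the pixel-count ratio so the image mean is conserved. This is
#' the ideal low-pass resampler: a pure harmonic inside the kept band is
#' reproduced exactly on the coarser grid.
#'
#' @param plane numeric matrix without missing values (fill no-data with the
#'   plane mean beforehand).
#' @param targetShape integer (rows, cols), elementwise \code{<=}
#'   \code{dim(plane)}.
#' @return Numeric matrix of the target shape.
#' @export
fourierResamplePlane <- function(plane, targetShape) {
  n <- dim(plane)
  m <- as.integer(targetShape)
  if (any(m > n)) stop("Fourier-crop resampling cannot upsample")
  if (anyNA(plane)) stop("plane contains missing values; fill them first")
  if (all(m == n)) return(plane)
  S <- .fftshift2(stats::fft(plane))
  cs <- floor(n / 2) + 1
  ridx <- (cs[1] - floor(m[1] / 2)):(cs[1] + ceiling(m[1] / 2) - 1)
  cidx <- (cs[2] - floor(m[2] / 2)):(cs[2] + ceiling(m[2] / 2) - 1)
  crop <- .ifftshift2(S[ridx, cidx, drop = FALSE])
  Re(stats::fft(crop, inverse = TRUE)) / prod(n)
}

#' Resample every wavenumber plane of a cube by Fourier cropping
#'
#' @param cube an \linkS4class{FtirCube} (no missing values).
#' @param targetShape integer (rows, cols) of the elemental grid.
#' @return The resampled \linkS4class{FtirCube}; the spectral axis is
#'   untouched.
#' @export
resampleCube <- function(cube, targetShape) {
  stopifnot(is(cube, "FtirCube"))
  d <- dim(cube@absorbance)
  m <- as.integer(targetShape)
  out <- array(0, dim = c(m, d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- fourierResamplePlane(cube@absorbance[, , k], m)
  scale <- sqrt(prod(d[1:2]) / prod(m))
  initialize(cube, absorbance = out, pixelSize = cube@pixelSize * scale)
}

#' Largest bin factor keeping the cube above a target shape
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param targetShape integer (rows, cols).
#' @return Integer bin factor >= 1.
#' @export
autoBinFactor <- function(cube, targetShape) {
  d <- dim(cube@absorbance)
  f <- min(d[1] %/% targetShape[1], d[2] %/% targetShape[2])
  if (f < 1) stop("cube smaller than the target shape")
  as.integer(f)
}

#' Register an FTIR cube onto the elemental grid
#'
#' Chains \code{\link{rotateCube}} (user-supplied theta),
#' \code{\link{binCube}} (given or automatic factor: the largest keeping
#' both dimensions at or above the target, "slightly above" the elemental
#' image), and \code{\link{resampleCube}}. No-data pixels created by the
#' rotation are filled with the plane mean before the Fourier step (hard
#' zeros would ring) and re-flagged afterwards via nearest-pixel mapping of
#' the validity mask.
#'
#' @param cube an \linkS4class{FtirCube}.
#' @param theta rotation in degrees (e.g. 2).
#' @param targetShape integer (rows, cols) of the elemental image.
#' @param binFactor integer or "auto".
#' @param mask optional rows x cols logical matrix of valid pixels (e.g.
#'   the preprocessing usable & SNR mask). Invalid pixels are treated like
#'   rotation no-data: excluded from the averaging and flagged in the
#'   output. Without this, spectra whose amide area was near zero (bare
#'   substrate) carry arbitrarily amplified noise from the scaling step
#'   into the low-resolution grid.
#' @return The registered \linkS4class{FtirCube} on the target grid, with
#'   \code{NA} at pixels whose support fell outside the field of view or
#'   the validity mask.
#' @export
registerCube <- function(cube, theta, targetShape, binFactor = "auto",
                         mask = NULL) {
  stopifnot(is(cube, "FtirCube"))
  targetShape <- as.integer(targetShape)
  if (!is.null(mask)) {
    d <- dim(cube@absorbance)
    stopifnot(identical(dim(mask), d[1:2]))
    if (!all(mask)) {
      a <- cube@absorbance
      a[array(rep(!mask, d[3]), dim = d)] <- NA
      cube <- initialize(cube, absorbance = a)
    }
  }
  rot <- rotateCube(cube, theta)
  f <- if (identical(binFactor, "auto")) autoBinFactor(rot, targetShape)
       else as.integer(binFactor)
  b <- binCube(rot, f)
  db <- dim(b@absorbance)
  if (any(db[1:2] < targetShape))
    stop("binned shape is below the target; reduce the bin factor")
  valid <- !is.na(b@absorbance[, , 1])
  if (!all(valid)) {
    a <- b@absorbance
    for (k in seq_len(db[3])) {
      pl <- a[, , k]
      pl[is.na(pl)] <- mean(pl, na.rm = TRUE)
      a[, , k] <- pl
    }
    b <- initialize(b, absorbance = a)
  }
  rs <- resampleCube(b, targetShape)
  if (!all(valid)) {
    mapR <- pmin(pmax(ceiling((seq_len(targetShape[1]) - 0.5) *
                                db[1] / targetShape[1]), 1), db[1])
    mapC <- pmin(pmax(ceiling((seq_len(targetShape[2]) - 0.5) *
                                db[2] / targetShape[2]), 1), db[2])
    outValid <- valid[mapR, mapC, drop = FALSE]
    a <- rs@absorbance
    a[array(rep(!outValid, dim(a)[3]), dim = dim(a))] <- NA
    rs <- initialize(rs, absorbance = a)
  }
  rs
}
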
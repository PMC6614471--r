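# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; no binary fixtures.

fullAxis <- function() seq(4000, 700, by = -4)      # 826 points
fusedAxis <- function() seq(1800, 900, by = -4)     # 226 points

## small cube with per-pixel spectra given as a pixel x wn matrix (row-major)
cubeFromSpectra <- function(spectra, rows, cols, wn) {
  a <- aperm(array(t(spectra), dim = c(length(wn), cols, rows)), c(3, 2, 1))
  FtirCube(a, wn)
}

## row-major pixel x wn matrix from a cube (oracle-side flattening)
spectraFromCube <- function(cube) {
  a <- absorbance(cube)
  d <- dim(a)
  matrix(aperm(a, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

## trapezoid area oracle over [lo, hi] with endpoint snapping
trapzOracle <- function(y, wn, lo, hi, localLine = FALSE) {
  i1 <- which.min(abs(wn - lo)); i2 <- which.min(abs(wn - hi))
  idx <- seq(min(i1, i2), max(i1, i2))
  x <- wn[idx]; yy <- y[idx]
  a <- sum(abs(diff(x)) * (head(yy, -1) + tail(yy, -1)) / 2)
  if (localLine) {
    n <- length(idx)
    a <- a - (yy[1] + yy[n]) / 2 * abs(x[n] - x[1])
  }
  a
}

## brute-force per-pair Pearson oracle
pearsonOracle <- function(x) {
  p <- ncol(x)
  r <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    r[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  r
}

## smooth band-limited test plane: integer-cycle low-frequency cosines
## (exactly representable in the DFT, so Fourier-domain operations on the
## plane are leakage-free)
smoothPlane <- function(n, seed = 1) {
  set.seed(seed)
  r <- (seq_len(n) - 1) / n; c <- (seq_len(n) - 1) / n
  p <- matrix(0, n, n)
  for (i in 1:3) {
    p <- p + outer(cos(2 * pi * sample(1:2, 1) * r + runif(1, 0, 2 * pi)),
                   cos(2 * pi * sample(1:2, 1) * c + runif(1, 0, 2 * pi)))
  }
  p / max(abs(p))
}

## neutral-element abundances: identical values on every tissue class so the
## elemental fields carry no FTIR-coupled class structure
neutralClassElements <- function(level = 4) {
  m <- defaultClassElements()
  m[2:4, ] <- matrix(rep(c(5, 2, 3, 1, 1, 2, 1, 1.5, level), each = 3),
                     nrow = 3)
  m[2:4, "64Zn"] <- level
  m
}

## Dice coefficient of two logical masks
diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

## Jaccard index
jaccardIndex <- function(a, b) sum(a & b) / sum(a | b)

## adjusted Rand index (mclust when present, else simple contingency form)
ariIndex <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
  exp_ <- ai * bj / choose(n, 2)
  (sumij - exp_) / ((ai + bj) / 2 - exp_)
}
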
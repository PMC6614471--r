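# Minimal ENVI header + flat-binary reader/writer for hyperspectral cubes.
# Supports BSQ/BIL/BIP interleaves, float32/float64 samples, either byte
# order; the band axis comes from the header "wavelength" field.

.parseEnviHeader <- function(hdrPath) {
  txt <- readLines(hdrPath, warn = FALSE)
  if (length(txt) == 0 || !grepl("^ENVI", txt[1]))
    stop("not an ENVI header (missing ENVI magic): ", hdrPath)
  body <- paste(txt[-1], collapse = "\n")
  # join brace-delimited multi-line values
  fields <- list()
  lines <- strsplit(body, "\n")[[1]]
  i <- 1
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!grepl("=", ln)) { i <- i + 1; next }
    key <- tolower(trimws(sub("=.*", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("\\}", val) && i < length(lines)) {
        i <- i + 1
        val <- paste(val, trimws(lines[i]))
      }
      val <- gsub("[{}]", "", val)
    }
    fields[[key]] <- trimws(val)
    i <- i + 1
  }
  fields
}

.enviNum <- function(fields, key, required = TRUE) {
  if (is.null(fields[[key]])) {
    if (required) stop("ENVI header missing required field: ", key)
    return(NULL)
  }
  as.numeric(fields[[key]])
}

.readEnviCube <- function(path) {
  hdrPath <- if (file.exists(paste0(path, ".hdr"))) paste0(path, ".hdr")
             else sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdrPath)) stop("ENVI header not found for ", path)
  if (!file.exists(path)) stop("ENVI binary not found: ", path)
  h <- .parseEnviHeader(hdrPath)
  ns <- as.integer(.enviNum(h, "samples"))
  nl <- as.integer(.enviNum(h, "lines"))
  nb <- as.integer(.enviNum(h, "bands"))
  dtype <- as.integer(.enviNum(h, "data type"))
  interleave <- tolower(if (is.null(h[["interleave"]])) "bsq" else h[["interleave"]])
  byteOrder <- as.integer(.enviNum(h, "byte order", required = FALSE))
  if (is.null(byteOrder) || is.na(byteOrder)) byteOrder <- 0L
  offset <- .enviNum(h, "header offset", required = FALSE)
  if (is.null(offset) || is.na(offset)) offset <- 0
  if (is.null(h[["wavelength"]]))
    stop("ENVI header has no wavelength field; band axis unknown")
  wl <- as.numeric(strsplit(h[["wavelength"]], ",")[[1]])
  if (length(wl) != nb) stop("wavelength list length does not match bands")
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type ", dtype,
                      " (only 4=float32, 5=float64)"))
  endian <- if (byteOrder == 0) "little" else "big"
  con <- file(path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", n = offset)
  vals <- readBin(con, "double", n = ns * nl * nb, size = size, endian = endian)
  if (length(vals) != ns * nl * nb) stop("ENVI binary truncated")
  a <- switch(interleave,
    bsq = aperm(array(vals, dim = c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(vals, dim = c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(vals, dim = c(nb, ns, nl)), c(3L, 2L, 1L)),
    stop("unsupported interleave: ", interleave))
  list(absorbance = a, wavenumbers = wl)
}

.writeEnviCube <- function(cube, path) {
  a <- cube@absorbance
  d <- dim(a)
  hdrPath <- paste0(path, ".hdr")
  wl <- paste(format(cube@wavenumbers, trim = TRUE, digits = 15), collapse = ", ")
  hdr <- c("ENVI",
           "description = {specfuse FTIR absorbance cube}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = Wavenumber",
           sprintf("wavelength = {%s}", wl))
  writeLines(hdr, hdrPath)
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: band-major, line-major within band, samples fastest
  writeBin(as.vector(aperm(a, c(2L, 1L, 3L))), con, size = 8, endian = "little")
  invisible(path)
}
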
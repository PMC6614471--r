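# End-to-end orchestration: synthetic scene (or files) -> FTIR preprocessing
# -> elemental preprocessing -> registration -> fusion -> chemometrics,
# with a resolved-config JSON run log and deterministic outputs.

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: SNR gates 150 (500 for
#' double clustering), rotation 2 degrees, 180 x 180 stitching frame,
#' 5-fold element replication, K = 4 feature clusters, 10 K-means restarts.
#'
#' @param seed master seed funneled to every stochastic step.
#' @param outDir output directory (default: a fresh temporary directory).
#' @return Named list of configuration values.
#' @export
defaultRunConfig <- function(seed = 1, outDir = tempfile("specfuse_run_")) {
  list(
    seed = seed,
    outDir = outDir,
    scene = list(),                    # overrides for makeScene()
    theta = 2,
    targetArea = 100,
    snrThreshold = 150,
    doubleClusterSnr = 500,
    replicate = 5,
    K = 4,
    restarts = 10,
    nPc = 10,
    stitchFrame = c(180, 180),
    backgroundCorner = 6,              # corner square (LA pixels) used as
                                       # the no-tissue background region
    writePlots = FALSE)
}

.loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- defaultRunConfig()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  if (is.null(base$theta)) stop("configuration is missing required field: theta")
  base
}

## corner background rectangles (top-left and bottom-right) on a grid
.cornerRegions <- function(rows, cols, k, frame) {
  RegionSet(rbind(c(0, 0, k, k),
                  c(rows - k, cols - k, k, k)), frame = frame)
}

#' Run the full fusion pipeline on a synthetic scene
#'
#' Generates the paired scene, applies the five-step FTIR correction chain,
#' the elemental background subtraction and standardization, registers the
#' FTIR cube onto the elemental grid (rotation, binning, Fourier-crop
#' resampling), fuses the two blocks with element replication, subtracts
#' the section background, standardizes per feature, and runs correlation
#' mapping, uncentered PCA and double clustering. Outputs (correlation
#' matrix, loadings, scores, fused container, JSON run log) are written to
#' \code{config$outDir}; a rerun with an identical configuration and seed
#' is file-for-file identical.
#'
#' @param config list or YAML path; see \code{\link{defaultRunConfig}} for
#'   the recognized fields and defaults.
#' @return Invisibly, a list with every intermediate product and the paths
#'   of the written files.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  cfg <- .loadConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  sceneArgs <- cfg$scene
  sceneArgs$seed <- cfg$seed
  if (is.null(sceneArgs$theta)) sceneArgs$theta <- cfg$theta
  scene <- do.call(makeScene, sceneArgs)

  cube <- renderFtir(scene)
  wvRef <- waterVaporReference(wavenumbers(cube))
  pp <- preprocessFtir(cube, wvRef, targetArea = cfg$targetArea,
                       snrThreshold = cfg$snrThreshold)

  img <- renderElements(scene)
  la <- dim(img)[1:2]
  k <- min(cfg$backgroundCorner, floor(min(la) / 4))
  laBg <- .cornerRegions(la[1], la[2], k, frame = "element")
  img <- subtractLaBackground(img, laBg)
  img <- standardizeElementImage(img)
  tMask <- tissueMask(img)

  reg <- registerCube(pp$cube, theta = scene@theta, targetShape = la,
                      mask = pp$mask)
  regSnr <- computeSnr(reg, threshold = cfg$snrThreshold)

  ftirF <- cropInterpolateFtir(reg)
  elF <- flattenElementImage(img)
  fused <- concatenateFeatures(ftirF, elF, replicate = cfg$replicate,
                               snr = as.vector(t(snrValues(regSnr))),
                               tissue = as.vector(t(tMask)))
  fusedBg <- .cornerRegions(la[1], la[2], k, frame = "fused")
  fused <- subtractFusedBackground(fused, fusedBg)
  fusedStd <- standardizeFused(fused, snrThreshold = cfg$snrThreshold,
                               zeroVariance = "keep")

  corr <- correlationMap(fusedStd, snrThreshold = cfg$snrThreshold)
  blocks <- crossBlockSummary(corr)
  pca <- pcaSpectra(fusedStd, center = FALSE, nPc = cfg$nPc,
                    snrThreshold = cfg$snrThreshold)
  dc <- tryCatch(
    doubleCluster(fusedStd, K = cfg$K, snrThreshold = cfg$doubleClusterSnr,
                  seed = cfg$seed, restarts = cfg$restarts),
    error = function(e) {
      warning("double clustering skipped: ", conditionMessage(e))
      NULL
    })

  files <- c(
    fused = file.path(cfg$outDir, "fused.rds"),
    correlation = file.path(cfg$outDir, "correlation.csv"),
    loadings = file.path(cfg$outDir, "loadings.csv"),
    scores = file.path(cfg$outDir, "scores.csv"),
    log = file.path(cfg$outDir, "run_log.json"))
  writeFused(fusedStd, files["fused"])
  utils::write.csv(corr@matrix, files["correlation"], row.names = FALSE)
  utils::write.csv(loadings(pca), files["loadings"], row.names = FALSE)
  utils::write.csv(scores(pca), files["scores"], row.names = FALSE)

  retained <- retainedPixels(fusedStd, cfg$snrThreshold)
  log <- list(
    config = cfg[setdiff(names(cfg), "outDir")],
    counts = list(
      ftirPixels = prod(dim(cube)[1:2]),
      elementPixels = prod(la),
      backgroundRegionPixels = sum(.regionMask(laBg, la[1], la[2])),
      tissuePixels = sum(tMask),
      retainedPixels = sum(retained),
      doubleClusterPixels = if (is.null(dc)) 0L else length(dc@spectrumOrder),
      features = ncol(fusedValues(fusedStd))),
    crossBlock = blocks,
    varianceFraction = varianceFraction(pca))
  jsonlite::write_json(log, files["log"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  if (isTRUE(cfg$writePlots)) {
    png <- file.path(cfg$outDir, "score_map_pc1.png")
    grDevices::png(png, width = 480, height = 480)
    sc <- matrix(NA_real_, la[1], la[2])
    sc[pixelCoords(fusedStd)[retained, , drop = FALSE]] <- scores(pca)[, 1]
    graphics::image(t(sc)[, la[1]:1], main = "PC1 score map", axes = FALSE)
    grDevices::dev.off()
    files <- c(files, scoreMap = png)
  }

  invisible(list(scene = scene, preprocess = pp, elements = img,
                 registered = reg, fused = fused, fusedStd = fusedStd,
                 correlation = corr, crossBlock = blocks, pca = pca,
                 doubleCluster = dc, files = files, config = cfg))
}
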
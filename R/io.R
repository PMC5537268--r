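## Stacks are stored as multi-page 16-bit TIFF (one plane per emission bin or
## filter channel, ascending wavelength) with a JSON metadata sidecar
## (`<path>.json`) carrying excitation, pixel size and bin edges or channel
## bands.  12-bit gray levels round-trip exactly through the 16-bit samples.

sidecarPath <- function(path) paste0(path, ".json")

#' Write a spectral stack or filter image to disk
#'
#' @param x A \linkS4class{SpectralStack} or \linkS4class{MultiChannelImage}.
#' @param path output TIFF path; metadata goes to \code{<path>.json}.
#' @return invisibly, \code{path}.
#' @export
writeStack <- function(x, path) {
  d <- x@data
  planes <- lapply(seq_len(dim(d)[3]), function(k) d[, , k] / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none")
  meta <- if (is(x, "SpectralStack")) {
    list(mode = "spectral", excitation = x@excitation,
         binEdges = x@binEdges, pixelSize = x@pixelSize)
  } else if (is(x, "MultiChannelImage")) {
    list(mode = "filter", excitation = x@excitation,
         channelBands = unname(apply(x@channelBands, 1, as.list)),
         pixelSize = x@pixelSize)
  } else stop("unsupported object of class ", class(x)[1])
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack written by \code{\link{writeStack}}
#'
#' Dispatches on the sidecar metadata: spectral mode yields a
#' \linkS4class{SpectralStack} (exactly 25 planes required), filter mode a
#' \linkS4class{MultiChannelImage} (3 planes).  Missing metadata keys and
#' plane-count mismatches are errors naming the problem.
#'
#' @param path TIFF path with a \code{<path>.json} sidecar.
#' @return A \linkS4class{SpectralStack} or \linkS4class{MultiChannelImage}.
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- sidecarPath(path)
  if (!file.exists(sp)) stop("missing metadata sidecar: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (key in c("mode", "excitation", "pixelSize"))
    if (is.null(meta[[key]])) stop("metadata is missing required key '", key, "'")
  planes <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, c(dim(planes[[1]]), length(planes)))
  for (k in seq_along(planes))
    arr[, , k] <- as.integer(round(planes[[k]] * 65535))
  if (meta$mode == "spectral") {
    if (is.null(meta$binEdges)) stop("metadata is missing required key 'binEdges'")
    if (dim(arr)[3] != 25L)
      stop("expected 25 bins for a spectral stack, found ", dim(arr)[3], " planes")
    new("SpectralStack", data = arr, excitation = meta$excitation,
        binEdges = as.numeric(meta$binEdges), pixelSize = meta$pixelSize)
  } else if (meta$mode == "filter") {
    if (is.null(meta$channelBands)) stop("metadata is missing required key 'channelBands'")
    if (dim(arr)[3] != 3L)
      stop("expected 3 planes for a filter-mode image, found ", dim(arr)[3])
    cb <- meta$channelBands  # list of {center, width} rows, or a data.frame
    bands <- if (is.data.frame(cb)) as.matrix(cb[, c("center", "width")])
             else do.call(rbind, lapply(cb, function(b)
               c(center = b$center, width = b$width)))
    dimnames(bands) <- dimnames(FILTER_BANDS)
    new("MultiChannelImage", data = arr, channelBands = bands,
        excitation = meta$excitation, pixelSize = meta$pixelSize)
  } else stop("unknown stack mode '", meta$mode, "'")
}

## Run-length encoding of logical masks for the JSON scene sidecar.
rleEncodeMask <- function(m) {
  r <- rle(as.vector(m))
  list(dims = dim(m), lengths = r$lengths, values = as.integer(r$values))
}

rleDecodeMask <- function(enc) {
  v <- inverse.rle(list(lengths = as.integer(enc$lengths),
                        values = as.logical(enc$values)))
  matrix(v, enc$dims[1], enc$dims[2])
}

#' Write a tissue scene (ground truth) as JSON
#'
#' Nuclei and duct tables are stored verbatim; masks are run-length encoded;
#' collagen density is stored as RLE of its distinct values.
#'
#' @param scene A \linkS4class{TissueScene}.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
writeScene <- function(scene, path) {
  r <- rle(as.vector(scene@collagenDensity))
  obj <- list(label = scene@label, widthUm = scene@widthUm,
              heightUm = scene@heightUm, pixelSize = scene@pixelSize,
              blurSigma = scene@blurSigma,
              nuclei = scene@nuclei, ducts = scene@ducts,
              masks = list(epithelium = rleEncodeMask(scene@epitheliumMask),
                           membrane = rleEncodeMask(scene@membraneMask),
                           immune = rleEncodeMask(scene@immuneMask),
                           goblet = rleEncodeMask(scene@gobletMask),
                           fibrosis = rleEncodeMask(scene@fibrosisMask),
                           nucleus = rleEncodeMask(scene@nucleusMask)),
              collagenDensity = list(dims = dim(scene@collagenDensity),
                                     lengths = r$lengths, values = r$values))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tissue scene written by \code{\link{writeScene}}
#'
#' @param path JSON path.
#' @return A \linkS4class{TissueScene}.
#' @export
readScene <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cd <- matrix(inverse.rle(list(lengths = as.integer(o$collagenDensity$lengths),
                                values = as.numeric(o$collagenDensity$values))),
               o$collagenDensity$dims[1], o$collagenDensity$dims[2])
  nuc <- as.data.frame(o$nuclei)
  if (!nrow(nuc))
    nuc <- data.frame(centerX = numeric(0), centerY = numeric(0),
                      majorAxis = numeric(0), minorAxis = numeric(0),
                      orientation = numeric(0))
  new("TissueScene", label = o$label, widthUm = o$widthUm,
      heightUm = o$heightUm, pixelSize = o$pixelSize, blurSigma = o$blurSigma,
      nuclei = nuc, ducts = as.data.frame(o$ducts),
      epitheliumMask = rleDecodeMask(o$masks$epithelium),
      membraneMask = rleDecodeMask(o$masks$membrane),
      immuneMask = rleDecodeMask(o$masks$immune),
      gobletMask = rleDecodeMask(o$masks$goblet),
      fibrosisMask = rleDecodeMask(o$masks$fibrosis),
      nucleusMask = rleDecodeMask(o$masks$nucleus),
      collagenDensity = cd)
}

RESULTS_COLUMNS <- c("imageId", "roiX", "roiY", "roiSide", "indexN", "nNuclei",
                     "indexS", "subwindowX", "subwindowY", "predicted", "truth")

#' Write a per-area results table as CSV
#'
#' Fixed header, full float precision, deterministic row order (image id,
#' then ROI origin).  Omitted areas are retained with
#' \code{predicted = "OMITTED"}.
#'
#' @param results data.frame with the columns produced by
#'   \code{\link{runPipeline}}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeResults <- function(results, path) {
  stopifnot(all(RESULTS_COLUMNS %in% names(results)))
  r <- results[, RESULTS_COLUMNS, drop = FALSE]
  r <- r[order(r$imageId, r$roiX, r$roiY), , drop = FALSE]
  con <- file(path, open = "wb")  # binary: fixed newlines across platforms
  on.exit(close(con))
  writeLines(paste(RESULTS_COLUMNS, collapse = ","), con)
  if (nrow(r)) {
    fmt <- function(v) {
      if (is.numeric(v)) vapply(v, function(x)
        if (is.na(x)) "NA" else format(x, digits = 17, scientific = FALSE), "")
      else as.character(v)
    }
    cells <- vapply(r, fmt, character(nrow(r)))
    if (nrow(r) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a results table written by \code{\link{writeResults}}
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readResults <- function(path) {
  r <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(RESULTS_COLUMNS %in% names(r)))
    stop("results file is missing required columns")
  r
}

## ---------------------------------------------------------------------------
## Run configuration: JSON on disk, fail-fast validation, lossless
## round-trip, provenance hash.

runConfigDefaults <- function()
  list(pixelSize = 0.5,
       thresholds = list(nMax = 9.5, sMin = 3.1),
       roi = list(side = 100, count = 5, seed = 1L),
       acquisition = list(gain = 1, readNoiseSd = 2, bitDepth = 12L),
       phantom = list(preset = "clean", label = "NORMAL", seed = 1L),
       outputDir = ".", logLevel = "info")

validateKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key", if (length(bad) > 1) "s", " in ", where,
         ": ", paste(bad, collapse = ", "))
}

#' Build a validated run configuration
#'
#' Merges overrides into the defaults; unknown keys are rejected fail-fast at
#' every level.
#'
#' @param ... named overrides of the default configuration (top-level keys:
#'   \code{pixelSize}, \code{thresholds}, \code{roi}, \code{acquisition},
#'   \code{phantom}, \code{outputDir}, \code{logLevel}).
#' @return list of class \code{"nlmpmConfig"}.
#' @export
runConfig <- function(...) {
  ov <- list(...)
  def <- runConfigDefaults()
  validateKeys(ov, names(def), "configuration")
  cfg <- modifyList(def, ov)
  validateKeys(cfg$thresholds, c("nMax", "sMin"), "thresholds")
  validateKeys(cfg$roi, c("side", "count", "seed"), "roi")
  validateKeys(cfg$acquisition, c("gain", "readNoiseSd", "bitDepth"), "acquisition")
  validateKeys(cfg$phantom,
               c("preset", "label", "seed", "widthUm", "heightUm",
                 "nucleusDiameterMean", "nucleusDiameterSd", "nDucts",
                 "membraneCollagenDensity", "membraneLossFraction",
                 "gobletFraction", "fibrosisFraction", "immuneDensity",
                 "blurSigma"),
               "phantom")
  structure(cfg, class = "nlmpmConfig")
}

#' Write a run configuration as JSON
#' @param cfg configuration from \code{\link{runConfig}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeRunConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate a run configuration
#' @param path JSON path.
#' @return list of class \code{"nlmpmConfig"}.
#' @export
readRunConfig <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  o$roi$seed <- as.integer(o$roi$seed)
  if (!is.null(o$phantom$seed)) o$phantom$seed <- as.integer(o$phantom$seed)
  if (!is.null(o$acquisition$bitDepth))
    o$acquisition$bitDepth <- as.integer(o$acquisition$bitDepth)
  do.call(runConfig, o)
}

#' Provenance hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; recorded in outputs so a results
#' table can be traced to the exact configuration that produced it.
#'
#' @param cfg configuration from \code{\link{runConfig}}.
#' @return character MD5 hash.
#' @export
configHash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeRunConfig(cfg, f)
  unname(tools::md5sum(f))
}
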
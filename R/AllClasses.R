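#' @import methods
#' @importFrom stats pnorm rnorm rpois runif t.test wilcox.test
#' @importFrom utils read.csv write.csv modifyList
NULL

## Supported two-photon excitation wavelengths (nm).  730/820/900 are the
## spectral-analysis lines; 780 drives the three-filter imaging mode.
SUPPORTED_EXCITATIONS <- c(730, 780, 820, 900)

## Emission detection grid: 25 contiguous 10-nm bins spanning 400-650 nm.
SPECTRAL_BIN_EDGES <- seq(400, 650, by = 10)

## 12-bit digitisation ceiling.
INTENSITY_MAX <- 4095L

## The three detection band-pass filters, centre/full-width (nm).
FILTER_BANDS <- matrix(c(417, 60, 480, 40, 629, 56), ncol = 2, byrow = TRUE,
                       dimnames = list(c("bp417", "bp480", "bp629"),
                                       c("center", "width")))

#' FluorophoreModel: an endogenous emitter
#'
#' Describes one endogenous signal source: a Gaussian fluorescence emitter
#' (NAD(P)H, FAD), a broadband uniform emitter (lipofuscin-like material,
#' diffuse background), or second-harmonic generation (SHG) by aligned
#' collagen, which emits at exactly half the excitation wavelength.
#'
#' @slot name character, one of \code{"NADPH"}, \code{"FAD"},
#'   \code{"LIPOFUSCIN"}, \code{"BACKGROUND"}, \code{"SHG"}.
#' @slot kind character, \code{"gaussian"}, \code{"uniform"} or \code{"shg"}.
#' @slot peakCenter numeric, Gaussian emission peak (nm); unused otherwise.
#' @slot peakWidthSigma numeric, Gaussian sigma (nm); for \code{"uniform"}
#'   the slots \code{rangeLo}/\code{rangeHi} apply instead.
#' @slot rangeLo,rangeHi numeric, support of a uniform emitter (nm).
#' @slot excitationEfficiency named numeric in [0,1], relative two-photon
#'   excitation efficiency per supported excitation wavelength.
#' @export
setClass("FluorophoreModel",
  representation(name = "character", kind = "character",
                 peakCenter = "numeric", peakWidthSigma = "numeric",
                 rangeLo = "numeric", rangeHi = "numeric",
                 excitationEfficiency = "numeric"),
  prototype(peakCenter = NA_real_, peakWidthSigma = NA_real_,
            rangeLo = NA_real_, rangeHi = NA_real_))

setValidity("FluorophoreModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("gaussian", "uniform", "shg"))
    msg <- c(msg, "kind must be 'gaussian', 'uniform' or 'shg'")
  eff <- object@excitationEfficiency
  if (is.null(names(eff)) || !all(names(eff) %in% as.character(SUPPORTED_EXCITATIONS)))
    msg <- c(msg, "excitationEfficiency must be named by supported excitation wavelengths")
  if (any(eff < 0 | eff > 1)) msg <- c(msg, "excitation efficiencies must lie in [0,1]")
  if (!any(eff > 0)) msg <- c(msg, "at least one excitation efficiency must be nonzero")
  if (object@kind == "gaussian" &&
      (!is.finite(object@peakCenter) || !is.finite(object@peakWidthSigma) ||
       object@peakWidthSigma <= 0))
    msg <- c(msg, "gaussian emitters need a finite peakCenter and positive peakWidthSigma")
  if (object@kind == "uniform" &&
      (!is.finite(object@rangeLo) || !is.finite(object@rangeHi) ||
       object@rangeHi <= object@rangeLo))
    msg <- c(msg, "uniform emitters need rangeLo < rangeHi")
  if (length(msg)) msg else TRUE
})

#' PhantomParams: configuration of a synthetic tissue scene
#'
#' All geometry is specified in micrometres and converted to pixels once,
#' using \code{pixelSize}.  The seed fixes every random draw so a scene is
#' bit-reproducible.
#'
#' @slot label character, \code{"NORMAL"} or \code{"CANCER"}.
#' @slot widthUm,heightUm numeric, field of view (um).
#' @slot pixelSize numeric, um per pixel.
#' @slot nucleusDiameterMean,nucleusDiameterSd numeric, the planted
#'   major-axis distribution (um), truncated at zero.
#' @slot nDucts integer, number of ductal structures.
#' @slot membraneCollagenDensity numeric in [0,1], aligned-collagen density
#'   of the basement membrane (and of fibrosis patches, when present).
#' @slot membraneLossFraction numeric in [0,1], fraction of basement-membrane
#'   arc removed (cancerous membrane breakdown).
#' @slot gobletFraction numeric in [0,1], probability that an epithelial void
#'   slot holds a goblet-cell mucin droplet instead of a nucleus.
#' @slot fibrosisFraction numeric in [0,1], approximate fraction of stromal
#'   area covered by fibrotic collagen patches.
#' @slot immuneDensity numeric, immune cells per 1000 um^2 of stroma.
#' @slot blurSigma numeric, acquisition blur (um, Gaussian sigma).
#' @slot photonGain numeric, detector gain applied to Poisson shot noise.
#' @slot readNoiseSd numeric, additive Gaussian read noise (gray levels).
#' @slot seed integer, fixes all randomness.
#' @export
setClass("PhantomParams",
  representation(label = "character", widthUm = "numeric", heightUm = "numeric",
                 pixelSize = "numeric",
                 nucleusDiameterMean = "numeric", nucleusDiameterSd = "numeric",
                 nDucts = "integer", membraneCollagenDensity = "numeric",
                 membraneLossFraction = "numeric", gobletFraction = "numeric",
                 fibrosisFraction = "numeric", immuneDensity = "numeric",
                 blurSigma = "numeric", photonGain = "numeric",
                 readNoiseSd = "numeric", seed = "integer"))

setValidity("PhantomParams", function(object) {
  msg <- character()
  if (!object@label %in% c("NORMAL", "CANCER"))
    msg <- c(msg, "label must be 'NORMAL' or 'CANCER'")
  if (object@nucleusDiameterMean <= 0)
    msg <- c(msg, "nucleusDiameterMean must be > 0")
  if (object@nucleusDiameterSd < 0) msg <- c(msg, "nucleusDiameterSd must be >= 0")
  fr <- c(object@membraneCollagenDensity, object@membraneLossFraction,
          object@gobletFraction, object@fibrosisFraction)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions/densities must lie in [0,1]")
  if (object@widthUm <= 0 || object@heightUm <= 0 || object@pixelSize <= 0)
    msg <- c(msg, "field dimensions and pixelSize must be positive")
  if (object@nDucts < 1L) msg <- c(msg, "nDucts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' TissueScene: ground-truth phantom geometry
#'
#' Raster masks share the dimensions implied by the field of view and pixel
#' size (rows = y, columns = x).  \code{nuclei} is the planted ground truth:
#' one row per nucleus with centre (um), axes (um) and orientation (rad).
#' \code{collagenDensity} is nonzero only on the membrane and fibrosis masks.
#'
#' @slot label character, true tissue class.
#' @slot widthUm,heightUm,pixelSize numeric, geometry (um, um, um/px).
#' @slot blurSigma numeric, acquisition blur carried to the renderer (um).
#' @slot nuclei data.frame with columns centerX, centerY, majorAxis,
#'   minorAxis, orientation.
#' @slot ducts data.frame with columns centerX, centerY, innerRadius,
#'   outerRadius, irregularity.
#' @slot epitheliumMask,membraneMask,immuneMask,gobletMask,fibrosisMask,nucleusMask
#'   logical matrices.
#' @slot collagenDensity numeric matrix in [0,1].
#' @export
setClass("TissueScene",
  representation(label = "character", widthUm = "numeric", heightUm = "numeric",
                 pixelSize = "numeric", blurSigma = "numeric",
                 nuclei = "data.frame", ducts = "data.frame",
                 epitheliumMask = "matrix", membraneMask = "matrix",
                 immuneMask = "matrix", gobletMask = "matrix",
                 fibrosisMask = "matrix", nucleusMask = "matrix",
                 collagenDensity = "matrix"))

setValidity("TissueScene", function(object) {
  msg <- character()
  nr <- round(object@heightUm / object@pixelSize)
  nc <- round(object@widthUm / object@pixelSize)
  masks <- list(object@epitheliumMask, object@membraneMask, object@immuneMask,
                object@gobletMask, object@fibrosisMask, object@nucleusMask,
                object@collagenDensity)
  for (m in masks)
    if (!all(dim(m) == c(nr, nc))) {
      msg <- c(msg, "all rasters must match the dimensions implied by the field of view")
      break
    }
  if (nrow(object@nuclei)) {
    idx <- umToPixelIndex(object@nuclei$centerX, object@nuclei$centerY,
                          object@pixelSize, nr, nc)
    if (!all(object@epitheliumMask[idx]))
      msg <- c(msg, "every nucleus centre must lie inside the epithelium mask")
  }
  off <- !(object@membraneMask | object@fibrosisMask)
  if (any(object@collagenDensity[off] != 0))
    msg <- c(msg, "collagenDensity must be zero off the membrane and fibrosis masks")
  if (any(object@collagenDensity < 0 | object@collagenDensity > 1))
    msg <- c(msg, "collagenDensity must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' SpectralStack: per-pixel 25-bin emission spectra at one excitation
#'
#' @slot data integer array rows x cols x 25, clipped to [0, 4095].
#' @slot excitation numeric, excitation wavelength (nm).
#' @slot binEdges numeric length 26, 400 + 10k nm for k = 0..25.
#' @slot pixelSize numeric, um per pixel.
#' @export
setClass("SpectralStack",
  representation(data = "array", excitation = "numeric",
                 binEdges = "numeric", pixelSize = "numeric"))

setValidity("SpectralStack", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L || d[3] != 25L)
    msg <- c(msg, "data must be a rows x cols x 25 array (exactly 25 emission bins)")
  if (length(object@binEdges) != 26L ||
      any(abs(diff(object@binEdges) - 10) > 1e-9))
    msg <- c(msg, "binEdges must be 26 ascending wavelengths with exact 10 nm spacing")
  if (!object@excitation %in% SUPPORTED_EXCITATIONS)
    msg <- c(msg, "excitation must be one of 730, 780, 820, 900 nm")
  rng <- range(object@data)
  if (rng[1] < 0 || rng[2] > INTENSITY_MAX)
    msg <- c(msg, "intensities must lie in [0, 4095]")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' MultiChannelImage: three-filter-channel acquisition
#'
#' @slot data integer array rows x cols x 3, clipped to [0, 4095].
#' @slot channelBands numeric matrix 3 x 2 (center, width in nm).
#' @slot excitation numeric, excitation wavelength (nm), 780 by default.
#' @slot pixelSize numeric, um per pixel.
#' @export
setClass("MultiChannelImage",
  representation(data = "array", channelBands = "matrix",
                 excitation = "numeric", pixelSize = "numeric"))

setValidity("MultiChannelImage", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "data must be a rows x cols x 3 array")
  if (!all(dim(object@channelBands) == c(3L, 2L)))
    msg <- c(msg, "channelBands must be a 3 x 2 (center, width) matrix")
  rng <- range(object@data)
  if (rng[1] < 0 || rng[2] > INTENSITY_MAX)
    msg <- c(msg, "intensities must lie in [0, 4095]")
  if (!object@excitation %in% SUPPORTED_EXCITATIONS)
    msg <- c(msg, "excitation must be one of 730, 780, 820, 900 nm")
  if (length(msg)) msg else TRUE
})

#' SquareROI: an axis-aligned square region of interest
#'
#' Physical coordinates in micrometres; origin at the image's top-left pixel
#' corner, x rightward, y downward.  Pixel membership is by pixel-centre
#' inclusion, half-open on the right/bottom edge.
#'
#' @slot originX,originY numeric, top-left corner (um).
#' @slot side numeric, side length (um), > 0.
#' @export
setClass("SquareROI",
  representation(originX = "numeric", originY = "numeric", side = "numeric"))

setValidity("SquareROI", function(object) {
  if (object@side <= 0) "side must be > 0" else TRUE
})

#' EmissionSpectrum: a 25-bin ROI-mean emission spectrum
#'
#' @slot intensities numeric length 25, non-negative.
#' @slot binEdges numeric length 26.
#' @slot excitation numeric (nm).
#' @export
setClass("EmissionSpectrum",
  representation(intensities = "numeric", binEdges = "numeric",
                 excitation = "numeric"))

setValidity("EmissionSpectrum", function(object) {
  msg <- character()
  if (length(object@intensities) != 25L) msg <- c(msg, "intensities must have length 25")
  if (any(object@intensities < 0)) msg <- c(msg, "intensities must be non-negative")
  if (length(object@binEdges) != 26L || is.unsorted(object@binEdges, strictly = TRUE))
    msg <- c(msg, "binEdges must be 26 ascending wavelengths")
  if (length(msg)) msg else TRUE
})

#' IndexS: SHG band-ratio statistic
#'
#' Ratio of the ROI-mean emission intensity at 410-420 nm to that at
#' 420-430 nm under 820 nm excitation; high where basement-membrane SHG is
#' present.
#'
#' @slot value numeric, dimensionless ratio >= 0.
#' @slot roi SquareROI the value was computed in.
#' @slot excitation numeric, must be 820.
#' @slot subwindow SquareROI or NULL; when the index is aggregated over a
#'   larger area, the winning 15-um subwindow.
#' @export
setClass("IndexS",
  representation(value = "numeric", roi = "SquareROI",
                 excitation = "numeric", subwindow = "ANY"),
  prototype(subwindow = NULL))

setValidity("IndexS", function(object) {
  msg <- character()
  if (object@excitation != 820) msg <- c(msg, "index S is defined only under 820 nm excitation")
  if (object@value < 0) msg <- c(msg, "value must be >= 0")
  if (length(msg)) msg else TRUE
})

#' IndexN: mean nuclear diameter in an ROI
#'
#' Arithmetic mean of the major-axis diameters of signal-void nuclear regions
#' whose centroids fall inside the ROI.  When no nucleus qualifies the index
#' is the sentinel OMITTED (value NA, nNuclei 0): the area is excluded from
#' classification, not an error.
#'
#' @slot value numeric (um), NA when omitted.
#' @slot nNuclei integer, number of contributing nuclei.
#' @slot roi SquareROI.
#' @export
setClass("IndexN",
  representation(value = "numeric", nNuclei = "integer", roi = "SquareROI"))

setValidity("IndexN", function(object) {
  if (object@nNuclei >= 1L && !(is.finite(object@value) && object@value > 0))
    "value must be positive when nNuclei >= 1" else TRUE
})

#' ConfusionMatrix: 2x2 classification counts, cancer as the positive class
#'
#' @slot tp,fp,tn,fn integer counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fp = "integer", tn = "integer", fn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  if (any(c(object@tp, object@fp, object@tn, object@fn) < 0L))
    "counts must be non-negative" else TRUE
})

#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))
#' @export
setGeneric("excitation", function(x) standardGeneric("excitation"))
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @export
setGeneric("channelBands", function(x) standardGeneric("channelBands"))
#' @export
setGeneric("sceneLabel", function(x) standardGeneric("sceneLabel"))
#' @export
setGeneric("sceneNuclei", function(x) standardGeneric("sceneNuclei"))
#' @export
setGeneric("indexValue", function(x) standardGeneric("indexValue"))
#' @export
setGeneric("isOmitted", function(x) standardGeneric("isOmitted"))

#' @describeIn SpectralStack raw intensity array (rows x cols x bins).
#' @param x object.
#' @export
setMethod("stackData", "SpectralStack", function(x) x@data)
#' @describeIn MultiChannelImage raw intensity array (rows x cols x 3).
#' @param x object.
#' @export
setMethod("stackData", "MultiChannelImage", function(x) x@data)
#' @export
setMethod("excitation", "SpectralStack", function(x) x@excitation)
#' @export
setMethod("excitation", "MultiChannelImage", function(x) x@excitation)
#' @export
setMethod("excitation", "EmissionSpectrum", function(x) x@excitation)
#' @export
setMethod("pixelSize", "SpectralStack", function(x) x@pixelSize)
#' @export
setMethod("pixelSize", "MultiChannelImage", function(x) x@pixelSize)
#' @export
setMethod("pixelSize", "TissueScene", function(x) x@pixelSize)
#' @export
setMethod("binEdges", "SpectralStack", function(x) x@binEdges)
#' @export
setMethod("binEdges", "EmissionSpectrum", function(x) x@binEdges)
#' @export
setMethod("channelBands", "MultiChannelImage", function(x) x@channelBands)
#' @export
setMethod("sceneLabel", "TissueScene", function(x) x@label)
#' @export
setMethod("sceneNuclei", "TissueScene", function(x) x@nuclei)
#' @export
setMethod("indexValue", "IndexS", function(x) x@value)
#' @export
setMethod("indexValue", "IndexN", function(x) x@value)
#' @export
setMethod("isOmitted", "IndexN", function(x) x@nNuclei == 0L)

setMethod("show", "SpectralStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpectralStack: %d x %d px, 25 bins %g-%g nm, excitation %g nm, %g um/px\n",
              d[1], d[2], object@binEdges[1], object@binEdges[26],
              object@excitation, object@pixelSize))
})

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object@data)
  bands <- apply(object@channelBands, 1, function(b) sprintf("%g/%g", b[1], b[2]))
  cat(sprintf("MultiChannelImage: %d x %d px, bands %s nm, excitation %g nm\n",
              d[1], d[2], paste(bands, collapse = ", "), object@excitation))
})

setMethod("show", "TissueScene", function(object) {
  cat(sprintf("TissueScene (%s): %g x %g um at %g um/px, %d ducts, %d nuclei\n",
              object@label, object@widthUm, object@heightUm, object@pixelSize,
              nrow(object@ducts), nrow(object@nuclei)))
})

setMethod("show", "SquareROI", function(object) {
  cat(sprintf("SquareROI: origin (%g, %g) um, side %g um\n",
              object@originX, object@originY, object@side))
})

setMethod("show", "IndexS", function(object) {
  cat(sprintf("Index S = %.3f (820 nm, ROI %g um at (%g, %g))\n", object@value,
              object@roi@side, object@roi@originX, object@roi@originY))
})

setMethod("show", "IndexN", function(object) {
  if (isOmitted(object))
    cat("Index N: OMITTED (no epithelial nuclei in ROI)\n")
  else
    cat(sprintf("Index N = %.2f um over %d nuclei\n", object@value, object@nNuclei))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (cancer = positive):\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(truth = c("cancer", "normal"),
                              predicted = c("cancer", "normal")))
  print(m)
})

#' Construct a SquareROI
#'
#' @param originX,originY top-left corner in micrometres.
#' @param side side length in micrometres.
#' @return A \linkS4class{SquareROI}.
#' @export
SquareROI <- function(originX, originY, side)
  new("SquareROI", originX = originX, originY = originY, side = side)
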
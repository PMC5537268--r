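#' Classification thresholds
#'
#' Normal tissue is defined by index N <= \code{nMax} AND index S >
#' \code{sMin}; any area failing either criterion is deemed cancerous.
#' Defaults 9.5 um and 3.1 are the published operating point.
#'
#' @param nMax maximum normal mean nuclear diameter (um).
#' @param sMin minimum normal SHG band ratio (exclusive).
#' @return list with elements \code{nMax}, \code{sMin}.
#' @export
thresholds <- function(nMax = 9.5, sMin = 3.1) {
  stopifnot(nMax > 0, sMin > 0)
  list(nMax = nMax, sMin = sMin)
}

#' Pre-registered placement of classification ROIs
#'
#' Draws non-overlapping square ROIs from the raster-aligned grid of
#' side-by-side cells by a seeded shuffle.  Placement depends only on the
#' image dimensions, ROI side, count and seed — never on image content — so
#' the areas are determined in advance of any measurement.
#'
#' @param imageWidth,imageHeight image extent (um).
#' @param side ROI side (um), default 100.
#' @param count requested number of ROIs, default 5.
#' @param seed integer seed for the shuffle.
#' @return list of \linkS4class{SquareROI}; if fewer than \code{count} fit, as
#'   many as fit are returned with a warning.
#' @export
placeROIs <- function(imageWidth, imageHeight, side = 100, count = 5, seed = 1L) {
  nx <- floor(imageWidth / side + 1e-9)
  ny <- floor(imageHeight / side + 1e-9)
  if (nx < 1 || ny < 1) stop("image too small for a single ROI of side ", side)
  cells <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  ord <- withSeed(seed, sample.int(nrow(cells)))
  n <- min(count, nrow(cells))
  if (n < count)
    warning("only ", n, " non-overlapping ROIs of side ", side, " um fit; ",
            count, " requested")
  lapply(ord[seq_len(n)], function(k)
    SquareROI(cells$ix[k] * side, cells$iy[k] * side, side))
}

#' Two-index threshold classification of one area
#'
#' NORMAL iff index N <= nMax (inclusive) and index S > sMin (strict);
#' otherwise CANCER.  An omitted index N (no nuclei in the area) yields
#' OMITTED.  Comparisons use unrounded values.
#'
#' @param indexN numeric mean nuclear diameter (um), \code{NA} for omitted,
#'   or an \linkS4class{IndexN}.
#' @param indexS numeric band ratio, or an \linkS4class{IndexS}.
#' @param th thresholds, see \code{\link{thresholds}}.
#' @return \code{"NORMAL"}, \code{"CANCER"} or \code{"OMITTED"}.
#' @examples
#' classifyArea(7, 5)     # NORMAL
#' classifyArea(9.5, 3.1) # CANCER: S not strictly greater
#' @export
classifyArea <- function(indexN, indexS, th = thresholds()) {
  if (is(indexN, "IndexN")) indexN <- indexN@value
  if (is(indexS, "IndexS")) indexS <- indexS@value
  if (is.na(indexN)) return("OMITTED")
  if (indexN <= th$nMax && indexS > th$sMin) "NORMAL" else "CANCER"
}

#' Confusion matrix over classified areas
#'
#' Counts non-omitted areas with cancer as the positive class.
#'
#' @param results data.frame with columns \code{predicted} and \code{truth}
#'   (values \code{"NORMAL"}, \code{"CANCER"}, and for predictions
#'   \code{"OMITTED"}).
#' @return A \linkS4class{ConfusionMatrix}.
#' @export
confusion <- function(results) {
  if (!nrow(results))
    return(new("ConfusionMatrix", tp = 0L, fp = 0L, tn = 0L, fn = 0L))
  keep <- results$predicted != "OMITTED"
  p <- results$predicted[keep]; t <- results$truth[keep]
  new("ConfusionMatrix",
      tp = sum(p == "CANCER" & t == "CANCER"),
      fp = sum(p == "CANCER" & t == "NORMAL"),
      tn = sum(p == "NORMAL" & t == "NORMAL"),
      fn = sum(p == "NORMAL" & t == "CANCER"))
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,tn,fn counts, cancer as the positive class.
#' @return A \linkS4class{ConfusionMatrix}.
#' @export
confusionMatrix <- function(tp, fp, tn, fn)
  new("ConfusionMatrix", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))

#' Diagnostic accuracy metrics
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp), NPV
#' tn/(tn+fn), and Cohen's kappa from observed vs. chance agreement on the
#' 2x2 table.  A metric with a zero denominator is \code{NA} (undefined and
#' flagged in \code{undefined}), never coerced to 0.
#'
#' @param cm A \linkS4class{ConfusionMatrix}.
#' @return list with \code{sensitivity}, \code{specificity}, \code{ppv},
#'   \code{npv}, \code{kappa} (raw proportions), \code{undefined} (names of
#'   undefined metrics), and \code{rounded} (whole-percent proportions and
#'   2-dp kappa, the reporting convention).
#' @examples
#' metrics(confusionMatrix(tp = 77, fp = 10, tn = 54, fn = 3))$rounded
#' @export
metrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tp <- cm@tp; fp <- cm@fp; tn <- cm@tn; fn <- cm@fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  n <- tp + fp + tn + fn
  if (n > 0) {
    po <- (tp + tn) / n
    pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
    kap <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  } else kap <- NA_real_
  vals <- list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
               kappa = kap)
  vals$undefined <- names(vals)[vapply(vals, is.na, TRUE)]
  vals$rounded <- list(
    sensitivity = round(100 * sens), specificity = round(100 * spec),
    ppv = round(100 * ppv), npv = round(100 * npv), kappa = round(kap, 2))
  vals
}

#' Run the full two-index classification pipeline on one case
#'
#' Places pre-registered ROIs, computes index N (signal-void nuclear
#' morphometry on the 480/40 channel) and index S (max-tile SHG band ratio on
#' the 820 nm stack) per area, applies the threshold rule, and tallies the
#' confusion matrix and diagnostic metrics against the true label.
#'
#' @param filterImage A \linkS4class{MultiChannelImage} (morphometry input).
#' @param spectral820 A \linkS4class{SpectralStack} at 820 nm (index S
#'   input); required — index S is undefined without it.
#' @param truth true tissue label, \code{"NORMAL"} or \code{"CANCER"}.
#' @param th thresholds, see \code{\link{thresholds}}.
#' @param roiSide,roiCount,roiSeed ROI configuration (um, count, seed).
#' @param aggregate index-S aggregation over the area, see
#'   \code{\link{indexSForArea}}.
#' @param imageId identifier recorded in the results table.
#' @return list with \code{results} (one row per area: roi geometry, indices,
#'   nucleus count, winning subwindow, predicted, truth), \code{nuclei} (the
#'   detection table), \code{confusion} and \code{metrics}.
#' @export
runPipeline <- function(filterImage, spectral820, truth, th = thresholds(),
                        roiSide = 100, roiCount = 5, roiSeed = 1L,
                        aggregate = "max", imageId = "case") {
  if (missing(spectral820) || is.null(spectral820))
    stop("an 820 nm spectral stack is required: index S is undefined without it")
  stopifnot(is(filterImage, "MultiChannelImage"), is(spectral820, "SpectralStack"))
  if (spectral820@excitation != 820)
    stop("spectral stack must be acquired at 820 nm")
  if (abs(filterImage@pixelSize - spectral820@pixelSize) > 1e-9)
    stop("filter image and spectral stack must share the pixel size")
  truth <- match.arg(truth, c("NORMAL", "CANCER"))

  px <- filterImage@pixelSize
  d <- dim(filterImage@data)
  w <- d[2] * px; h <- d[1] * px
  rois <- placeROIs(w, h, side = roiSide, count = roiCount, seed = roiSeed)

  chan <- morphometryChannel(filterImage)
  mask <- segmentEpithelium(chan, px)
  nuclei <- detectNuclei(chan, mask, px)

  rows <- lapply(seq_along(rois), function(k) {
    roi <- rois[[k]]
    iN <- indexN(nuclei, roi)
    iS <- indexSForArea(spectral820, roi, aggregate = aggregate)
    data.frame(imageId = imageId, roiX = roi@originX, roiY = roi@originY,
               roiSide = roi@side,
               indexN = iN@value, nNuclei = iN@nNuclei, indexS = iS@value,
               subwindowX = iS@subwindow@originX,
               subwindowY = iS@subwindow@originY,
               predicted = classifyArea(iN, iS, th), truth = truth,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  cm <- confusion(results)
  list(results = results, nuclei = nuclei, confusion = cm, metrics = metrics(cm))
}

#' Scatter plot of classified areas in the (N, S) plane
#'
#' Plots index N against index S with the decision boundary (dashed) at the
#' thresholds; normal-truth areas as black dots, cancer-truth areas as red
#' triangles.
#'
#' @param results data.frame with columns \code{indexN}, \code{indexS},
#'   \code{truth} (omitted areas are dropped).
#' @param th thresholds, see \code{\link{thresholds}}.
#' @param ... passed to \code{plot}.
#' @return invisibly, the plotted data.frame.
#' @importFrom graphics abline legend points segments par
#' @export
plotIndexScatter <- function(results, th = thresholds(), ...) {
  ok <- !is.na(results$indexN)
  r <- results[ok, , drop = FALSE]
  pch <- ifelse(r$truth == "CANCER", 17, 16)
  col <- ifelse(r$truth == "CANCER", "red", "black")
  plot(r$indexN, r$indexS, pch = pch, col = col,
       xlab = "index N (mean nuclear diameter, um)",
       ylab = "index S (SHG band ratio)", ...)
  abline(h = th$sMin, lty = 2)
  abline(v = th$nMax, lty = 2)
  legend("topright", legend = c("normal", "cancer"), pch = c(16, 17),
         col = c("black", "red"), bty = "n")
  invisible(r)
}
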
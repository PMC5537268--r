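#' ROI-mean emission spectrum
#'
#' Per-bin arithmetic mean over all pixels whose centres fall inside the
#' square ROI (half-open on the right/bottom edge).
#'
#' @param stack A \linkS4class{SpectralStack}.
#' @param roi A \linkS4class{SquareROI} fully inside the raster.
#' @return An \linkS4class{EmissionSpectrum}.
#' @export
roiMeanSpectrum <- function(stack, roi) {
  stopifnot(is(stack, "SpectralStack"), is(roi, "SquareROI"))
  d <- dim(stack@data)
  rng <- roiPixelRange(roi, d[1], d[2], stack@pixelSize)
  sub <- stack@data[rng$rows, rng$cols, , drop = FALSE]
  new("EmissionSpectrum",
      intensities = apply(sub, 3, mean),
      binEdges = stack@binEdges, excitation = stack@excitation)
}

## Index of the bin covering [lo, lo+10) on the stack's grid.
binIndexFor <- function(binEdges, lo) {
  i <- which(abs(binEdges[-length(binEdges)] - lo) < 1e-9)
  if (!length(i)) stop("no emission bin starts at ", lo, " nm")
  i
}

#' Index S: the SHG band ratio
#'
#' The ROI-mean emission intensity at 410-420 nm divided by that at
#' 420-430 nm, under 820 nm excitation.  Aligned collagen's second harmonic
#' of 820 nm light lands at 410 nm, so an intact basement membrane drives the
#' ratio far above the flat autofluorescence baseline (ratio near 1).  The
#' denominator is floored at one gray level so dark ROIs stay finite.
#'
#' @param stack A \linkS4class{SpectralStack} acquired at 820 nm.
#' @param roi A \linkS4class{SquareROI}.
#' @return An \linkS4class{IndexS}.
#' @export
indexS <- function(stack, roi) {
  stopifnot(is(stack, "SpectralStack"))
  if (stack@excitation != 820)
    stop("index S is defined only under 820 nm excitation (stack is ",
         stack@excitation, " nm)")
  spec <- roiMeanSpectrum(stack, roi)
  num <- spec@intensities[binIndexFor(stack@binEdges, 410)]
  den <- spec@intensities[binIndexFor(stack@binEdges, 420)]
  new("IndexS", value = num / max(den, 1), roi = roi, excitation = 820)
}

#' Index S over a classification area
#'
#' Tiles the area with non-overlapping subwindows (15 um by default, the
#' side used for spectral ROIs), computes index S in each, and aggregates.
#' The default aggregation is the maximum: any intact stretch of basement
#' membrane inside the area yields a normal-like S.  A mean-of-top-3 variant
#' is available.  A single-tile area reduces to \code{\link{indexS}} on that
#' ROI.
#'
#' @param stack A \linkS4class{SpectralStack} at 820 nm.
#' @param area A \linkS4class{SquareROI} with side >= \code{subwindowSide}.
#' @param subwindowSide subwindow side (um), default 15.
#' @param aggregate \code{"max"} (default) or \code{"meanTop3"}.
#' @return An \linkS4class{IndexS}; its \code{subwindow} slot holds the
#'   winning subwindow.
#' @export
indexSForArea <- function(stack, area, subwindowSide = 15,
                          aggregate = c("max", "meanTop3")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is(area, "SquareROI"))
  if (area@side < subwindowSide)
    stop("area side must be >= subwindow side")
  nTiles <- floor(area@side / subwindowSide + 1e-9)
  vals <- matrix(NA_real_, nTiles, nTiles)
  rois <- vector("list", nTiles * nTiles)
  k <- 0L
  for (iy in seq_len(nTiles)) for (ix in seq_len(nTiles)) {
    k <- k + 1L
    roi <- SquareROI(area@originX + (ix - 1L) * subwindowSide,
                     area@originY + (iy - 1L) * subwindowSide,
                     subwindowSide)
    rois[[k]] <- roi
    vals[iy, ix] <- indexS(stack, roi)@value
  }
  v <- as.vector(t(vals))
  best <- which.max(v)
  value <- switch(aggregate,
    max = v[best],
    meanTop3 = mean(sort(v, decreasing = TRUE)[seq_len(min(3L, length(v)))]))
  new("IndexS", value = value, roi = area, excitation = 820,
      subwindow = rois[[best]])
}
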
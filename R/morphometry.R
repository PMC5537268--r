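## Otsu threshold of a median-smoothed intensity raster, on the raw
## gray-level scale.  Both the epithelium mask and the void detection use
## this single level, so no second free parameter exists.
otsuLevel <- function(image) {
  sm <- smoothRaster(image)
  if (diff(range(sm)) == 0) return(Inf)  # constant image: nothing is bright
  img01 <- EBImage::Image(sm / (INTENSITY_MAX + 1))
  EBImage::otsu(img01, range = c(0, 1), levels = INTENSITY_MAX + 1L) *
    (INTENSITY_MAX + 1)
}

smoothRaster <- function(image) {
  img01 <- EBImage::Image(pmin(pmax(image / (INTENSITY_MAX + 1), 0), 1))
  as.matrix(EBImage::medianFilter(img01, size = 1L)) * (INTENSITY_MAX + 1)
}

#' Segment fluorescent epithelium
#'
#' Masks the bright cytoplasmic tissue against which nuclear signal voids are
#' read: global Otsu threshold on a median-smoothed image, removal of small
#' objects (< 25 um^2), and closing of enclosed holes up to 400 um^2 so that
#' nuclear voids stay enclosed by the mask.  A constant image yields an empty
#' mask, not an error.
#'
#' @param image numeric matrix of intensities (gray levels).
#' @param pixelSize um per pixel.
#' @return Logical matrix; attribute \code{"threshold"} carries the Otsu
#'   level used.
#' @export
segmentEpithelium <- function(image, pixelSize) {
  stopifnot(is.matrix(image), length(image) > 0)
  thr <- otsuLevel(image)
  sm <- smoothRaster(image)
  bright <- sm > thr

  pxArea <- pixelSize^2
  if (any(bright)) {
    lab <- EBImage::bwlabel(EBImage::Image(bright * 1))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes * pxArea >= 25)
    bright <- matrix(as.integer(lab) %in% keep, nrow(image), ncol(image))
  }

  ## fill enclosed holes of area <= 400 um^2 (background components that do
  ## not touch the raster border)
  if (any(bright) && any(!bright)) {
    hlab <- EBImage::bwlabel(EBImage::Image((!bright) * 1))
    hmat <- matrix(as.integer(hlab), nrow(image), ncol(image))
    borderIds <- unique(c(hmat[1, ], hmat[nrow(image), ],
                          hmat[, 1], hmat[, ncol(image)]))
    sizes <- tabulate(as.vector(hmat))
    fill <- setdiff(which(sizes * pxArea <= 400), borderIds)
    if (length(fill)) bright[hmat %in% fill] <- TRUE
  }

  structure(bright, threshold = thr)
}

## TRUE for mask components that touch a pixel outside `region` (4-adjacency)
## or the raster border.
touchesOutside <- function(labels, region) {
  nr <- nrow(labels); nc <- ncol(labels)
  out <- !region
  ## dilate `out` by one pixel in the four cardinal directions
  d <- out
  d[-1, ] <- d[-1, ] | out[-nr, ]
  d[-nr, ] <- d[-nr, ] | out[-1, ]
  d[, -1] <- d[, -1] | out[, -nc]
  d[, -nc] <- d[, -nc] | out[, -1]
  touched <- unique(labels[d & labels > 0])
  border <- unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc]))
  union(touched, setdiff(border, 0L))
}

#' Detect nuclei as signal-void regions
#'
#' Nuclei appear as dark (below the global Otsu level) connected components
#' fully enclosed by the epithelium mask; components touching the mask border
#' are discarded so luminal space is never counted.  Each retained component
#' is summarised by the ellipse fitted from its second-order image moments;
#' components whose equivalent diameter falls outside
#' \code{[minDiam, maxDiam]} are dropped.
#'
#' @param image numeric matrix of intensities (gray levels), typically the
#'   480/40 nm channel (see \code{\link{morphometryChannel}}).
#' @param epitheliumMask logical matrix from \code{\link{segmentEpithelium}}.
#' @param pixelSize um per pixel.
#' @param minDiam,maxDiam equivalent-diameter gate (um), default 3-25.
#' @return data.frame with one row per nucleus: \code{centroidX},
#'   \code{centroidY} (um), \code{majorAxis}, \code{minorAxis} (um),
#'   \code{area} (um^2), \code{orientation} (rad).  Zero rows is a valid
#'   result.
#' @export
detectNuclei <- function(image, epitheliumMask, pixelSize,
                         minDiam = 3, maxDiam = 25) {
  stopifnot(all(dim(image) == dim(epitheliumMask)))
  empty <- data.frame(centroidX = numeric(0), centroidY = numeric(0),
                      majorAxis = numeric(0), minorAxis = numeric(0),
                      area = numeric(0), orientation = numeric(0))
  thr <- attr(epitheliumMask, "threshold")
  if (is.null(thr)) thr <- otsuLevel(image)
  if (!is.finite(thr)) return(empty)
  sm <- smoothRaster(image)
  cand <- (sm <= thr) & epitheliumMask
  if (!any(cand)) return(empty)

  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(cand * 1))),
                nrow(image), ncol(image))
  drop <- touchesOutside(lab, epitheliumMask)
  ids <- setdiff(seq_len(max(lab)), drop)
  if (!length(ids)) return(empty)

  rows <- lapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    fitMomentEllipse(px, pixelSize)
  })
  res <- do.call(rbind, rows)
  eqd <- 2 * sqrt(res$area / pi)
  res <- res[eqd >= minDiam & eqd <= maxDiam, , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Moment-ellipse fit of a pixel set: the ellipse with the same second-order
## moments as the component.  The px^2/12 term accounts for the finite pixel
## extent.  For a filled ellipse the major axis equals 4*sqrt(lambda_max).
fitMomentEllipse <- function(px, pixelSize) {
  x <- (px[, 2] - 0.5) * pixelSize
  y <- (px[, 1] - 0.5) * pixelSize
  mx <- mean(x); my <- mean(y)
  corr <- pixelSize^2 / 12
  sxx <- mean((x - mx)^2) + corr
  syy <- mean((y - my)^2) + corr
  sxy <- mean((x - mx) * (y - my))
  tr <- sxx + syy
  disc <- sqrt(max(0, (sxx - syy)^2 + 4 * sxy^2))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  data.frame(centroidX = mx, centroidY = my,
             majorAxis = 4 * sqrt(max(l1, 0)),
             minorAxis = 4 * sqrt(max(l2, 0)),
             area = nrow(px) * pixelSize^2,
             orientation = 0.5 * atan2(2 * sxy, sxx - syy))
}

#' Index N: mean nuclear diameter in an ROI
#'
#' Arithmetic mean of the major-axis diameters over nuclei whose centroids
#' fall inside the ROI (half-open pixel-centre inclusion).  An ROI containing
#' no nucleus yields the OMITTED sentinel (\code{nNuclei = 0}, value
#' \code{NA}); such areas are excluded from classification rather than
#' treated as errors.
#'
#' @param nuclei data.frame from \code{\link{detectNuclei}}.
#' @param roi A \linkS4class{SquareROI}.
#' @return An \linkS4class{IndexN}.
#' @export
indexN <- function(nuclei, roi) {
  stopifnot(is(roi, "SquareROI"))
  if (nrow(nuclei)) {
    inside <- nuclei$centroidX >= roi@originX &
      nuclei$centroidX < roi@originX + roi@side &
      nuclei$centroidY >= roi@originY &
      nuclei$centroidY < roi@originY + roi@side
    d <- nuclei$majorAxis[inside]
  } else d <- numeric(0)
  if (!length(d))
    new("IndexN", value = NA_real_, nNuclei = 0L, roi = roi)
  else
    new("IndexN", value = mean(d), nNuclei = length(d), roi = roi)
}

#' Compare nuclear-diameter distributions between groups
#'
#' Welch's t-test for Gaussian-like groups; if either group is highly skewed
#' (|sample skewness| > 1) the Mann-Whitney U-test is used instead.  The
#' report names the test that fired.
#'
#' @param normal,cancer numeric vectors of diameters (um), each of length
#'   >= 3.
#' @return list with \code{test} (\code{"welch"} or \code{"mann-whitney"}),
#'   \code{statistic}, \code{p.value}, and the group skewnesses.
#' @export
compareDiameterGroups <- function(normal, cancer) {
  if (length(normal) < 3 || length(cancer) < 3)
    stop("each group must contain at least 3 measurements")
  sk <- c(normal = sampleSkewness(normal), cancer = sampleSkewness(cancer))
  if (any(abs(sk) > 1)) {
    ht <- wilcox.test(normal, cancer, exact = FALSE)
    test <- "mann-whitney"
  } else {
    ht <- t.test(normal, cancer, var.equal = FALSE)
    test <- "welch"
  }
  list(test = test, statistic = unname(ht$statistic),
       p.value = ht$p.value, skewness = sk)
}

#' Morphometry channel of an acquisition
#'
#' The intensity raster nuclei are read from: the 480/40 nm channel of a
#' filter-mode image, or the summed 440-500 nm bins of a spectral stack —
#' where cytoplasmic NAD(P)H/FAD signal is strongest.
#'
#' @param x A \linkS4class{MultiChannelImage} or \linkS4class{SpectralStack}.
#' @return Numeric intensity matrix.
#' @export
morphometryChannel <- function(x) {
  if (is(x, "MultiChannelImage")) {
    x@data[, , 2]
  } else if (is(x, "SpectralStack")) {
    lo <- x@binEdges[-length(x@binEdges)]
    sel <- which(lo >= 440 - 1e-9 & lo < 500 - 1e-9)
    apply(x@data[, , sel, drop = FALSE], c(1, 2), sum)
  } else stop("unsupported input type: ", class(x)[1])
}
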
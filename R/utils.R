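## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Matrix index (row, col) of the pixel whose cell contains the physical
## point (x um rightward, y um downward); pixel (i, j) covers
## [(j-1)px, j*px) x [(i-1)px, i*px).
umToPixelIndex <- function(x, y, pixelSize, nrow, ncol) {
  j <- pmin(pmax(floor(x / pixelSize) + 1L, 1L), ncol)
  i <- pmin(pmax(floor(y / pixelSize) + 1L, 1L), nrow)
  cbind(i, j)
}

## Pixel-centre coordinate grids (um) for a raster.
pixelCenters <- function(nrow, ncol, pixelSize) {
  list(x = (seq_len(ncol) - 0.5) * pixelSize,
       y = (seq_len(nrow) - 0.5) * pixelSize)
}

## Row/column index ranges of pixels whose centres fall inside an ROI
## (half-open on the right/bottom edge).  Errors if the ROI leaves the
## raster or covers no pixel.
roiPixelRange <- function(roi, nrow, ncol, pixelSize) {
  x1 <- roi@originX; y1 <- roi@originY
  x2 <- x1 + roi@side; y2 <- y1 + roi@side
  if (x1 < 0 || y1 < 0 || x2 > ncol * pixelSize + 1e-9 ||
      y2 > nrow * pixelSize + 1e-9)
    stop("ROI extends outside the image raster")
  cols <- which((seq_len(ncol) - 0.5) * pixelSize >= x1 &
                (seq_len(ncol) - 0.5) * pixelSize < x2)
  rows <- which((seq_len(nrow) - 0.5) * pixelSize >= y1 &
                (seq_len(nrow) - 0.5) * pixelSize < y2)
  if (!length(rows) || !length(cols)) stop("ROI covers no pixel centre")
  list(rows = rows, cols = cols)
}

## Sample skewness g1 = m3 / m2^(3/2).
sampleSkewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

## Clip to the 12-bit range and round to integer gray levels.
clip12bit <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > INTENSITY_MAX] <- INTENSITY_MAX
  storage.mode(x) <- "integer"
  x
}
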
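#' Construct phantom parameters
#'
#' Parameter set for one synthetic colorectal-mucosa scene.  Defaults encode
#' the contrasts of the two tissue classes: normal mucosa has near-circular
#' ducts, an intact collagen-rich basement membrane and ~7 um nuclei; cancer
#' has irregular duct boundaries, membrane breakdown and enlarged (~12 um)
#' nuclei.  See \code{\link{phantomPreset}} for the named study conditions.
#'
#' @param label \code{"NORMAL"} or \code{"CANCER"}.
#' @param widthUm,heightUm field of view (um).
#' @param pixelSize um per pixel (default 0.5).
#' @param nucleusDiameterMean,nucleusDiameterSd planted nuclear major-axis
#'   distribution (um), truncated positive.
#' @param nDucts number of ductal structures.
#' @param membraneCollagenDensity aligned-collagen density in [0,1] on the
#'   basement membrane (SHG amplitude scales with its square).
#' @param membraneLossFraction fraction of membrane arc removed.
#' @param gobletFraction probability an epithelial void slot is a goblet-cell
#'   mucin droplet rather than a nucleus.
#' @param fibrosisFraction approximate fraction of stroma covered by fibrotic
#'   collagen patches.
#' @param immuneDensity immune cells per 1000 um^2 of stroma.
#' @param blurSigma acquisition blur (um).
#' @param photonGain detector gain for the shot-noise model.
#' @param readNoiseSd additive Gaussian read noise (gray levels).
#' @param seed integer seed fixing all randomness.
#' @return A \linkS4class{PhantomParams}.
#' @export
PhantomParams <- function(label = c("NORMAL", "CANCER"),
                          widthUm = 300, heightUm = 300, pixelSize = 0.5,
                          nucleusDiameterMean = if (label == "NORMAL") 7 else 12,
                          nucleusDiameterSd = if (label == "NORMAL") 1 else 1.5,
                          nDucts = 4L,
                          membraneCollagenDensity = 1.0,
                          membraneLossFraction = if (label == "NORMAL") 0 else 1,
                          gobletFraction = 0, fibrosisFraction = 0,
                          immuneDensity = 0.8,
                          blurSigma = 0.25, photonGain = 1, readNoiseSd = 2,
                          seed = 1L) {
  label <- match.arg(label)
  new("PhantomParams", label = label, widthUm = widthUm, heightUm = heightUm,
      pixelSize = pixelSize, nucleusDiameterMean = nucleusDiameterMean,
      nucleusDiameterSd = nucleusDiameterSd, nDucts = as.integer(nDucts),
      membraneCollagenDensity = membraneCollagenDensity,
      membraneLossFraction = membraneLossFraction,
      gobletFraction = gobletFraction, fibrosisFraction = fibrosisFraction,
      immuneDensity = immuneDensity, blurSigma = blurSigma,
      photonGain = photonGain, readNoiseSd = readNoiseSd,
      seed = as.integer(seed))
}

#' Named phantom presets
#'
#' The study conditions exercised by the pipeline: \code{"clean"} scenes with
#' the full class contrast, and the three documented failure modes —
#' \code{"blurred"} (acquisition blur smears the SHG band and obscures small
#' nuclei, pushing normal areas toward a cancer call), \code{"goblet"}
#' (mucin droplets read as enlarged signal-void "nuclei", inflating index N
#' in normal tissue), and \code{"fibrosis"} (stromal collagen in a tumour
#' with only moderately enlarged nuclei restores a high index S, pushing
#' cancer areas toward a normal call).
#'
#' @param preset one of \code{"clean"}, \code{"blurred"}, \code{"goblet"},
#'   \code{"fibrosis"}.
#' @param label tissue class; \code{"blurred"}/\code{"goblet"} default NORMAL,
#'   \code{"fibrosis"} defaults CANCER.
#' @param seed integer seed.
#' @param ... overrides passed to \code{\link{PhantomParams}}.
#' @return A \linkS4class{PhantomParams}.
#' @export
phantomPreset <- function(preset = c("clean", "blurred", "goblet", "fibrosis"),
                          label = NULL, seed = 1L, ...) {
  preset <- match.arg(preset)
  if (is.null(label))
    label <- switch(preset, fibrosis = "CANCER",
                    clean = "NORMAL", "NORMAL")
  args <- switch(preset,
    clean = list(),
    blurred = list(blurSigma = 2.0),
    goblet = list(gobletFraction = 0.5),
    fibrosis = list(nucleusDiameterMean = 9.0, nucleusDiameterSd = 1.0,
                    membraneLossFraction = 1, fibrosisFraction = 0.35))
  do.call(PhantomParams,
          modifyList(c(list(label = label, seed = seed), args), list(...)))
}

## ---------------------------------------------------------------------------
## Geometry sampling.  All random draws happen here, in physical (um)
## coordinates, independent of the raster resolution, so the same seed gives
## the same physical scene at any pixel size.

MEMBRANE_THICKNESS_UM <- 2

## Boundary-modulation function for a duct: 1 + A * sum_k a_k sin(k theta + p_k)
ductShapeFun <- function(amp) {
  k <- 2:5
  a <- abs(rnorm(4)); a <- a / sum(a)
  p <- runif(4, 0, 2 * pi)
  function(theta)
    1 + amp * colSums(a * sin(outer(k, theta) + p))
}

sampleGeometry <- function(p) {
  gx <- ceiling(sqrt(p@nDucts))
  gy <- ceiling(p@nDucts / gx)
  cellW <- p@widthUm / gx
  cellH <- p@heightUm / gy
  outerR <- 0.38 * min(cellW, cellH)
  if (outerR < 8)
    stop("raster too small to hold one duct (duct radius would be ",
         round(outerR, 1), " um)")
  innerR <- 0.42 * outerR
  irreg <- if (p@label == "CANCER") 0.30 else 0.04

  ducts <- list(); nuclei <- list(); goblets <- list()
  idx <- 0L
  for (iy in seq_len(gy)) for (ix in seq_len(gx)) {
    if (idx >= p@nDucts) break
    idx <- idx + 1L
    cx <- (ix - 0.5) * cellW + runif(1, -0.03, 0.03) * cellW
    cy <- (iy - 0.5) * cellH + runif(1, -0.03, 0.03) * cellH
    shape <- ductShapeFun(irreg)
    ## membrane-loss arcs: random starts, total angular span = loss * 2pi
    loss <- p@membraneLossFraction
    if (loss >= 1) {
      arcs <- cbind(start = 0, len = 2 * pi)
    } else if (loss > 0) {
      w <- abs(rnorm(3)); w <- w / sum(w) * loss * 2 * pi
      arcs <- cbind(start = runif(3, 0, 2 * pi), len = w)
    } else arcs <- cbind(start = numeric(0), len = numeric(0))

    ducts[[idx]] <- list(centerX = cx, centerY = cy, innerRadius = innerR,
                         outerRadius = outerR, irregularity = irreg,
                         shape = shape, arcs = arcs)

    ## epithelial void slots (nuclei / goblet cells) on a ring
    ringR <- innerR + 0.65 * (outerR - innerR)
    spacing <- 1.4 * p@nucleusDiameterMean
    nSlots <- max(1L, floor(2 * pi * ringR / spacing))
    thetas <- seq(0, 2 * pi, length.out = nSlots + 1L)[-1L] +
      runif(nSlots, -0.1, 0.1) * spacing / ringR
    for (t in thetas) {
      r <- ringR * shape(t)
      x <- cx + r * cos(t); y <- cy + r * sin(t)
      isGoblet <- p@gobletFraction > 0 && runif(1) < p@gobletFraction
      if (isGoblet) {
        d <- max(8, rnorm(1, 14, 1.5))
        if (x - d/2 < 0 || y - d/2 < 0 || x + d/2 > p@widthUm || y + d/2 > p@heightUm)
          next
        goblets[[length(goblets) + 1L]] <- c(x, y, d)
      } else {
        d <- rnorm(1, p@nucleusDiameterMean, p@nucleusDiameterSd)
        while (d <= 0.5) d <- rnorm(1, p@nucleusDiameterMean, p@nucleusDiameterSd)
        if (x - d/2 < 0 || y - d/2 < 0 || x + d/2 > p@widthUm || y + d/2 > p@heightUm)
          next
        nuclei[[length(nuclei) + 1L]] <-
          c(x, y, d, d * runif(1, 0.6, 0.75), t)
      }
    }
  }

  ## analytic point-in-region tests against the sampled ducts
  ductRegion <- function(x, y, outerMargin = MEMBRANE_THICKNESS_UM) {
    inside <- logical(length(x))
    for (d in ducts) {
      dx <- x - d$centerX; dy <- y - d$centerY
      r <- sqrt(dx^2 + dy^2); th <- atan2(dy, dx)
      inside <- inside | r < (d$outerRadius + outerMargin) * d$shape(th)
    }
    inside
  }

  ## immune cells: uniform over the stroma (rejection sampling)
  stromaArea <- max(0, p@widthUm * p@heightUm -
                      sum(vapply(ducts, function(d)
                        pi * (d$outerRadius + MEMBRANE_THICKNESS_UM)^2, 0)))
  nImmune <- round(p@immuneDensity * stromaArea / 1000)
  immune <- matrix(numeric(0), ncol = 3)
  if (nImmune > 0) {
    pts <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(pts) < nImmune && tries < 50L) {
      tries <- tries + 1L
      cand <- cbind(runif(nImmune * 2, 2, p@widthUm - 2),
                    runif(nImmune * 2, 2, p@heightUm - 2))
      keep <- !ductRegion(cand[, 1], cand[, 2])
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(min(nImmune, nrow(pts))), , drop = FALSE]
    immune <- cbind(pts, pmax(2, rnorm(nrow(pts), 4, 0.5)))
  }

  ## fibrosis: collagen blobs in the stroma until target coverage
  fib <- matrix(numeric(0), ncol = 3)
  if (p@fibrosisFraction > 0) {
    meanBlobArea <- pi * 13^2
    nBlob <- ceiling(p@fibrosisFraction * stromaArea / meanBlobArea)
    got <- 0L; tries <- 0L
    while (got < nBlob && tries < 60L * nBlob) {
      tries <- tries + 1L
      x <- runif(1, 10, p@widthUm - 10); y <- runif(1, 10, p@heightUm - 10)
      if (ductRegion(x, y)) next
      fib <- rbind(fib, c(x, y, runif(1, 9, 17)))
      got <- got + 1L
    }
  }

  list(ducts = ducts,
       nuclei = if (length(nuclei)) do.call(rbind, nuclei) else matrix(numeric(0), ncol = 5),
       goblets = if (length(goblets)) do.call(rbind, goblets) else matrix(numeric(0), ncol = 3),
       immune = immune, fibrosis = fib)
}

## ---------------------------------------------------------------------------
## Rasterisation (deterministic given the geometry).

rasterizeDisks <- function(mask, disks, px) {
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nrow(disks))) {
    cx <- disks[i, 1]; cy <- disks[i, 2]; rad <- disks[i, 3] / 2
    cols <- max(1L, floor((cx - rad) / px)):min(nc, ceiling((cx + rad) / px))
    rows <- max(1L, floor((cy - rad) / px)):min(nr, ceiling((cy + rad) / px))
    xs <- (cols - 0.5) * px; ys <- (rows - 0.5) * px
    sub <- outer(ys - cy, xs - cx, function(a, b) a^2 + b^2) <= rad^2
    mask[rows, cols] <- mask[rows, cols] | sub
  }
  mask
}

rasterizeEllipses <- function(mask, ells, px) {
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nrow(ells))) {
    cx <- ells[i, 1]; cy <- ells[i, 2]
    a <- ells[i, 3] / 2; b <- ells[i, 4] / 2; phi <- ells[i, 5]
    cols <- max(1L, floor((cx - a) / px)):min(nc, ceiling((cx + a) / px))
    rows <- max(1L, floor((cy - a) / px)):min(nr, ceiling((cy + a) / px))
    xs <- (cols - 0.5) * px - cx; ys <- (rows - 0.5) * px - cy
    dx <- matrix(xs, length(rows), length(cols), byrow = TRUE)
    dy <- matrix(ys, length(rows), length(cols))
    u <- (dx * cos(phi) + dy * sin(phi)) / a
    v <- (-dx * sin(phi) + dy * cos(phi)) / b
    mask[rows, cols] <- mask[rows, cols] | (u^2 + v^2 <= 1)
  }
  mask
}

#' Generate a ground-truth tissue scene
#'
#' Samples the physical geometry (ducts, basement-membrane arcs, nuclei,
#' goblet cells, immune cells, fibrosis patches) under the parameter seed and
#' rasterises it.  Geometry is sampled in micrometres independently of the
#' raster, so the same seed yields the same physical scene at any pixel size;
#' the whole call is bit-reproducible.
#'
#' @param params A \linkS4class{PhantomParams}.
#' @return A \linkS4class{TissueScene}.
#' @examples
#' sc <- generateScene(PhantomParams("NORMAL", seed = 42))
#' sc
#' @export
generateScene <- function(params) {
  stopifnot(is(params, "PhantomParams"))
  validObject(params)
  geom <- withSeed(params@seed, sampleGeometry(params))
  px <- params@pixelSize
  nr <- round(params@heightUm / px)
  nc <- round(params@widthUm / px)
  empty <- matrix(FALSE, nr, nc)
  cen <- pixelCenters(nr, nc, px)
  X <- matrix(cen$x, nr, nc, byrow = TRUE)
  Y <- matrix(cen$y, nr, nc)

  epi <- empty; mem <- empty
  for (d in geom$ducts) {
    dx <- X - d$centerX; dy <- Y - d$centerY
    r <- sqrt(dx^2 + dy^2)
    box <- r < (d$outerRadius + MEMBRANE_THICKNESS_UM) * (1 + d$irregularity) + px
    th <- atan2(dy[box], dx[box])
    s <- d$shape(th)
    rb <- r[box]
    epiSub <- rb >= d$innerRadius * s & rb < d$outerRadius * s
    memSub <- rb >= d$outerRadius * s &
      rb < (d$outerRadius + MEMBRANE_THICKNESS_UM) * s
    ## membrane breakdown: drop pixels whose angle falls in a loss arc
    if (nrow(d$arcs)) {
      lost <- rep(FALSE, length(th))
      for (k in seq_len(nrow(d$arcs)))
        lost <- lost | ((th - d$arcs[k, "start"]) %% (2 * pi)) < d$arcs[k, "len"]
      memSub <- memSub & !lost
    }
    e <- epi[box]; m <- mem[box]
    epi[box] <- e | epiSub
    mem[box] <- m | memSub
  }

  nucMask <- rasterizeEllipses(empty, geom$nuclei, px)
  gobMask <- rasterizeDisks(empty, geom$goblets, px)
  immMask <- rasterizeDisks(empty, geom$immune, px)
  stroma <- !(epi | mem)
  fibMask <- rasterizeDisks(empty, geom$fibrosis, px) & stroma

  dens <- matrix(0, nr, nc)
  dens[mem] <- params@membraneCollagenDensity
  dens[fibMask] <- params@membraneCollagenDensity

  nuclei <- as.data.frame(geom$nuclei)
  names(nuclei) <- c("centerX", "centerY", "majorAxis", "minorAxis", "orientation")
  ducts <- do.call(rbind, lapply(geom$ducts, function(d)
    data.frame(centerX = d$centerX, centerY = d$centerY,
               innerRadius = d$innerRadius, outerRadius = d$outerRadius,
               irregularity = d$irregularity)))

  new("TissueScene", label = params@label, widthUm = params@widthUm,
      heightUm = params@heightUm, pixelSize = px, blurSigma = params@blurSigma,
      nuclei = nuclei, ducts = ducts,
      epitheliumMask = epi, membraneMask = mem, immuneMask = immMask,
      gobletMask = gobMask, fibrosisMask = fibMask, nucleusMask = nucMask,
      collagenDensity = dens)
}

## ---------------------------------------------------------------------------
## Rendering.

#' Default emitter amplitudes
#'
#' Expected gray-level amplitude of each tissue component at unit excitation
#' efficiency (unit-normalised emission mass).  \code{nadph}/\code{fadEpi}
#' drive the epithelial cytoplasm, \code{fadImmune}/\code{lipofuscin} the
#' immune cells, \code{shg} the aligned-collagen second harmonic (scaled by
#' collagen density squared), and \code{background} a weak broadband
#' autofluorescence present everywhere.
#'
#' @return Named list of amplitudes.
#' @export
defaultAmplitudes <- function()
  list(nadph = 3000, fadEpi = 800, fadImmune = 2500, lipofuscin = 625,
       shg = 1200, background = 400)

## Per-component amplitude maps.  Nucleus and goblet interiors carry no
## emitter (signal voids); SHG amplitude scales with collagen density squared.
componentAmplitudeMaps <- function(scene, amplitudes) {
  cyto <- scene@epitheliumMask & !(scene@nucleusMask | scene@gobletMask)
  list(
    NADPH = amplitudes$nadph * cyto,
    FADepi = amplitudes$fadEpi * cyto,
    FADimm = amplitudes$fadImmune * scene@immuneMask,
    LIPOFUSCIN = amplitudes$lipofuscin * scene@immuneMask,
    SHG = amplitudes$shg * scene@collagenDensity^2,
    BACKGROUND = amplitudes$background +
      0 * scene@collagenDensity  # broadband floor over the whole field
  )
}

componentModel <- function(name) {
  lib <- fluorophoreLibrary()
  switch(name, NADPH = lib$NADPH, FADepi = lib$FAD, FADimm = lib$FAD,
         LIPOFUSCIN = lib$LIPOFUSCIN, SHG = lib$SHG,
         BACKGROUND = lib$BACKGROUND)
}

## Focus factor for second-harmonic generation.  SHG needs a tight,
## phase-matched focus: when the effective focal spot degrades from the
## diffraction-limited sigma0 to blurSigma, the generated harmonic falls off
## with the squared spot-size ratio, while incoherent fluorescence is merely
## smeared.  This is what makes blurred acquisitions lose their SHG band.
shgFocusFactor <- function(blurSigma, sigma0 = 1) 1 / (1 + (blurSigma / sigma0)^2)

## Expected (noise-free, unblurred, unclipped) emission over arbitrary bands.
expectedBands <- function(scene, excitation, lo, hi, amplitudes) {
  maps <- componentAmplitudeMaps(scene, amplitudes)
  nr <- nrow(scene@epitheliumMask); nc <- ncol(scene@epitheliumMask)
  out <- array(0, c(nr, nc, length(lo)))
  for (nm in names(maps)) {
    mass <- fluorophoreBandMass(componentModel(nm), excitation, lo, hi)
    if (all(mass == 0) || all(maps[[nm]] == 0)) next
    out <- out + outer(maps[[nm]], mass)
  }
  out
}

#' Expected spectral emission of a scene
#'
#' The noise-free, unblurred, unclipped per-pixel expected spectrum: the sum
#' over tissue components of amplitude times the component's per-bin
#' emission.  Serves as the analytic reference for the renderer (linearity,
#' SHG quadratic scaling).
#'
#' @param scene A \linkS4class{TissueScene}.
#' @param excitation excitation wavelength (nm).
#' @param amplitudes emitter amplitudes, see \code{\link{defaultAmplitudes}}.
#' @return Numeric array rows x cols x 25.
#' @export
expectedSpectral <- function(scene, excitation, amplitudes = defaultAmplitudes()) {
  edges <- SPECTRAL_BIN_EDGES
  expectedBands(scene, excitation, edges[1:25], edges[2:26], amplitudes)
}

applyNoiseBlurClip <- function(expected, scene, gain, readNoiseSd, seed, noise) {
  sig <- expected
  if (noise) {
    sig <- withSeed(seed, {
      shot <- gain * rpois(length(expected), as.vector(expected) / gain)
      shot + rnorm(length(expected), 0, readNoiseSd)
    })
    sig <- array(sig, dim(expected))
  }
  if (scene@blurSigma > 0) {
    sigmaPx <- scene@blurSigma / scene@pixelSize
    sig <- as.array(EBImage::gblur(EBImage::Image(sig), sigma = sigmaPx))
  }
  clip12bit(sig)
}

#' Render a multispectral stack from a scene
#'
#' Applies the acquisition model to the expected spectrum: gain-scaled
#' Poisson shot noise plus additive Gaussian read noise, then Gaussian blur
#' of the scene's \code{blurSigma}, then clipping to the 12-bit range.
#' Defocus additionally attenuates the coherent SHG component by the squared
#' focal-spot ratio (fluorescence is only smeared), so blurred acquisitions
#' lose their second-harmonic band.  Deterministic under a fixed seed.
#'
#' @param scene A \linkS4class{TissueScene}.
#' @param excitation excitation wavelength (nm), one of 730, 780, 820, 900.
#' @param gain detector gain for the shot-noise model.
#' @param readNoiseSd Gaussian read noise (gray levels).
#' @param seed integer seed for the noise draws.
#' @param noise set \code{FALSE} for a noise-free render (blur and clipping
#'   still apply).
#' @param amplitudes emitter amplitudes, see \code{\link{defaultAmplitudes}}.
#' @return A \linkS4class{SpectralStack}.
#' @examples
#' sc <- generateScene(PhantomParams("NORMAL", seed = 1))
#' st <- renderSpectral(sc, 820, seed = 1)
#' st
#' @export
renderSpectral <- function(scene, excitation, gain = 1, readNoiseSd = 2,
                           seed = 1L, noise = TRUE,
                           amplitudes = defaultAmplitudes()) {
  stopifnot(is(scene, "TissueScene"))
  acq <- modifyList(amplitudes,
                    list(shg = amplitudes$shg * shgFocusFactor(scene@blurSigma)))
  expected <- expectedSpectral(scene, excitation, acq)
  dat <- applyNoiseBlurClip(expected, scene, gain, readNoiseSd, seed, noise)
  new("SpectralStack", data = dat, excitation = excitation,
      binEdges = SPECTRAL_BIN_EDGES, pixelSize = scene@pixelSize)
}

#' Render a three-filter-channel image from a scene
#'
#' Excitation is fixed at 780 nm (the imaging configuration).  Each channel
#' integrates the per-pixel expected emission over its band-pass filter
#' (417/60, 480/40, 629/56 nm); the SHG harmonic at 390 nm falls inside the
#' 417/60 band only.  Noise, blur and clipping follow the same contract as
#' \code{\link{renderSpectral}}.
#'
#' @inheritParams renderSpectral
#' @return A \linkS4class{MultiChannelImage}.
#' @export
renderFilters <- function(scene, gain = 1, readNoiseSd = 2, seed = 1L,
                          noise = TRUE, amplitudes = defaultAmplitudes()) {
  stopifnot(is(scene, "TissueScene"))
  lo <- FILTER_BANDS[, "center"] - FILTER_BANDS[, "width"] / 2
  hi <- FILTER_BANDS[, "center"] + FILTER_BANDS[, "width"] / 2
  acq <- modifyList(amplitudes,
                    list(shg = amplitudes$shg * shgFocusFactor(scene@blurSigma)))
  expected <- expectedBands(scene, 780, lo, hi, acq)
  dat <- applyNoiseBlurClip(expected, scene, gain, readNoiseSd, seed, noise)
  new("MultiChannelImage", data = dat, channelBands = FILTER_BANDS,
      excitation = 780, pixelSize = scene@pixelSize)
}
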
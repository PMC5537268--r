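# A bright field with planted dark ellipses, built directly (no renderer).
plantedVoidImage <- function(nr = 120, nc = 120, bright = 800, dark = 50,
                             ellipses = NULL, pixelSize = 0.5) {
  img <- matrix(bright, nr, nc)
  if (!is.null(ellipses)) {
    for (i in seq_len(nrow(ellipses))) {
      e <- ellipses[i, ]
      for (r in 1:nr) for (cc in 1:nc) {
        dx <- (cc - e[1]); dy <- (r - e[2])
        u <- (dx * cos(e[5]) + dy * sin(e[5])) / e[3]
        v <- (-dx * sin(e[5]) + dy * cos(e[5])) / e[4]
        if (u^2 + v^2 <= 1) img[r, cc] <- dark
      }
    }
  }
  img
}

test_that("segmentation recovers the epithelium mask on noise-free phantoms", {
  s <- smallNormalScene(seed = 30)
  im <- renderFilters(s, noise = FALSE)
  ch <- morphometryChannel(im)
  mask <- segmentEpithelium(ch, s@pixelSize)
  gt <- s@epitheliumMask
  jaccard <- sum(mask & gt) / sum(mask | gt)
  expect_gte(jaccard, 0.95)
})

test_that("segmentation degenerates gracefully", {
  # all-dark image: empty mask, no error
  expect_true(all(!segmentEpithelium(matrix(0, 50, 50), 0.5)))
  # constant image: empty mask
  expect_true(all(!segmentEpithelium(matrix(1000, 50, 50), 0.5)))
  # a constant offset shifts the Otsu level, not the mask
  img <- plantedVoidImage(ellipses = rbind(c(60, 60, 10, 6, 0)))
  m1 <- segmentEpithelium(img, 0.5)
  m2 <- segmentEpithelium(img + 500, 0.5)
  attr(m1, "threshold") <- NULL  # the level itself follows the offset
  attr(m2, "threshold") <- NULL
  expect_identical(m1, m2)
})

test_that("a planted dark ellipse is measured at its analytic major axis", {
  # semi-axes 5 px and 3 px at 0.5 um/px: major axis 5.0 um
  img <- plantedVoidImage(ellipses = rbind(c(60, 60, 5, 3, 0.4)))
  mask <- segmentEpithelium(img, 0.5)
  det <- detectNuclei(img, mask, 0.5)
  expect_equal(nrow(det), 1L)
  expect_equal(det$majorAxis, 5.0, tolerance = 0.1)   # +- 0.5 um contract
  expect_equal(det$minorAxis, 3.0, tolerance = 0.17)
  expect_equal(det$centroidX, 29.75, tolerance = 0.02) # (col - 0.5) * px, um
})

test_that("uniform bright epithelium yields no detections", {
  img <- plantedVoidImage()  # no voids at all
  mask <- segmentEpithelium(img, 0.5)
  expect_equal(nrow(detectNuclei(img, mask, 0.5)), 0L)
})

test_that("voids touching the mask border are not counted as nuclei", {
  # a dark notch cut into the edge of the bright region is open to the
  # outside, unlike an enclosed void
  img <- matrix(50, 100, 100)
  img[20:80, 20:80] <- 800
  img[45:55, 20:28] <- 50    # notch open to the left border of the mask
  img[45:55, 50:58] <- 50    # enclosed void of the same size
  mask <- segmentEpithelium(img, 0.5)
  det <- detectNuclei(img, mask, 0.5)
  expect_equal(nrow(det), 1L)
  expect_gt(det$centroidX[1], 20)
})

test_that("planted nuclei are recovered with matched diameters (noise-free)", {
  s <- generateScene(PhantomParams("NORMAL", widthUm = 200, heightUm = 200,
                                   nDucts = 1L, immuneDensity = 0, seed = 31))
  gt <- sceneNuclei(s)
  expect_gte(nrow(gt), 30)
  im <- renderFilters(s, noise = FALSE)
  ch <- morphometryChannel(im)
  det <- detectNuclei(ch, segmentEpithelium(ch, s@pixelSize), s@pixelSize)
  m <- matchNuclei(det, gt)
  matched <- sum(!is.na(m))
  expect_gte(matched, round(0.96 * nrow(gt)))
  err <- det$majorAxis[!is.na(m)] - gt$majorAxis[m[!is.na(m)]]
  expect_true(all(abs(err) <= 2 * s@pixelSize))  # within a pixel or two
  expect_lt(abs(mean(err)), 0.25)
})

test_that("goblet-cell mucus is recognised as spurious signal-void detections", {
  s <- generateScene(PhantomParams("NORMAL", widthUm = 200, heightUm = 200,
                                   nDucts = 1L, immuneDensity = 0,
                                   gobletFraction = 0.5, seed = 32))
  expect_gt(sum(s@gobletMask), 0)
  im <- renderFilters(s, noise = FALSE)
  ch <- morphometryChannel(im)
  det <- detectNuclei(ch, segmentEpithelium(ch, s@pixelSize), s@pixelSize)
  # detections not matching any planted nucleus are goblet voids
  m <- matchNuclei(det, sceneNuclei(s))
  expect_gt(sum(is.na(m)), 0)
  # and they read larger than true nuclei, inflating index N
  expect_gt(mean(det$majorAxis[is.na(m)]), mean(sceneNuclei(s)$majorAxis))
})

test_that("measured major axis is stable under scene rotation", {
  # the same physical ellipse at 0 and 45 degrees
  d0 <- detectNuclei(img <- plantedVoidImage(ellipses = rbind(c(60, 60, 10, 6, 0))),
                     segmentEpithelium(img, 0.5), 0.5)
  d45 <- detectNuclei(img <- plantedVoidImage(ellipses = rbind(c(60, 60, 10, 6, pi / 4))),
                      segmentEpithelium(img, 0.5), 0.5)
  expect_lt(abs(d0$majorAxis - d45$majorAxis), 0.5)  # < 1 pixel
})

test_that("measured diameters are covariant with pixel size", {
  p1 <- PhantomParams("NORMAL", widthUm = 150, heightUm = 150, nDucts = 1L,
                      immuneDensity = 0, seed = 33, pixelSize = 0.5)
  p2 <- PhantomParams("NORMAL", widthUm = 150, heightUm = 150, nDucts = 1L,
                      immuneDensity = 0, seed = 33, pixelSize = 0.25)
  meas <- function(p) {
    s <- generateScene(p)
    ch <- morphometryChannel(renderFilters(s, noise = FALSE))
    det <- detectNuclei(ch, segmentEpithelium(ch, p@pixelSize), p@pixelSize)
    m <- matchNuclei(det, sceneNuclei(s))
    mean(det$majorAxis[!is.na(m)])
  }
  m1 <- meas(p1); m2 <- meas(p2)
  expect_lt(abs(m1 - m2) / m1, 0.02)
})

test_that("index N averages nuclei inside the ROI and omits empty areas", {
  nuc <- data.frame(centroidX = c(10, 20, 30, 90), centroidY = c(10, 20, 30, 90),
                    majorAxis = c(6, 7, 8, 20), minorAxis = c(4, 5, 6, 15),
                    area = c(20, 25, 30, 200), orientation = 0)
  iN <- indexN(nuc, SquareROI(0, 0, 50))
  expect_equal(indexValue(iN), 7.0)
  expect_equal(iN@nNuclei, 3L)
  om <- indexN(nuc, SquareROI(40, 40, 20))
  expect_true(isOmitted(om))
  expect_true(is.na(indexValue(om)))
  expect_true(isOmitted(indexN(nuc[0, ], SquareROI(0, 0, 50))))
})

test_that("cancer-scene index N lands on the ground-truth matched mean", {
  s <- generateScene(PhantomParams("CANCER", widthUm = 200, heightUm = 200,
                                   nDucts = 1L, immuneDensity = 0,
                                   nucleusDiameterMean = 12,
                                   nucleusDiameterSd = 1.5, seed = 34))
  ch <- morphometryChannel(renderFilters(s, noise = FALSE))
  det <- detectNuclei(ch, segmentEpithelium(ch, s@pixelSize), s@pixelSize)
  roi <- SquareROI(0, 0, 200)
  iN <- indexN(det, roi)
  expect_gte(iN@nNuclei, 20L)
  expect_gt(indexValue(iN), 11)
  expect_lt(indexValue(iN), 13)
})

test_that("group comparison picks the right test and detects separation", {
  x <- c(7.1, 6.9, 7.0, 7.2, 6.8)
  expect_gt(compareDiameterGroups(x, x)$p.value, 0.95)

  set.seed(99)
  a <- rnorm(100, 7, 1); b <- rnorm(100, 12, 1.5)
  rep <- compareDiameterGroups(a, b)
  expect_equal(rep$test, "welch")
  expect_lt(rep$p.value, 1e-6)
  # permutation oracle on a subsample confirms the separation is real
  aa <- a[1:30]; bb <- b[1:30]
  obs <- mean(bb) - mean(aa)
  pool <- c(aa, bb)
  perm <- replicate(2000, {
    i <- sample(60, 30)
    mean(pool[-i]) - mean(pool[i])
  })
  expect_lt(mean(abs(perm) >= abs(obs)), 0.001)

  skewed <- exp(rnorm(50, 0, 1.2))
  expect_equal(compareDiameterGroups(skewed, rnorm(50, 7, 1))$test, "mann-whitney")
  expect_error(compareDiameterGroups(c(1, 2), c(3, 4, 5)), "at least 3")
})
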
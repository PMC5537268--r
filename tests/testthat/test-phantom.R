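test_that("scene generation is bit-reproducible under a fixed seed", {
  p <- PhantomParams("NORMAL", nucleusDiameterMean = 7, nucleusDiameterSd = 1,
                     seed = 42)
  s1 <- generateScene(p)
  s2 <- generateScene(p)
  expect_identical(s1@nuclei, s2@nuclei)
  expect_identical(s1@epitheliumMask, s2@epitheliumMask)
  expect_identical(s1@collagenDensity, s2@collagenDensity)
  expect_identical(s1@immuneMask, s2@immuneMask)
})

test_that("scene geometry is sampled in physical units, independent of pixel size", {
  p1 <- PhantomParams("NORMAL", seed = 9, pixelSize = 0.5)
  p2 <- PhantomParams("NORMAL", seed = 9, pixelSize = 0.25)
  s1 <- generateScene(p1); s2 <- generateScene(p2)
  expect_identical(s1@nuclei, s2@nuclei)
  expect_identical(dim(s2@epitheliumMask), 2L * dim(s1@epitheliumMask))
})

test_that("complete membrane loss leaves zero collagen density", {
  s <- generateScene(PhantomParams("CANCER", membraneLossFraction = 1, seed = 5))
  expect_true(all(s@collagenDensity[s@membraneMask] == 0))
  expect_true(all(s@collagenDensity == 0))
})

test_that("planted nuclear diameters follow the configured distribution", {
  s <- generateScene(PhantomParams("NORMAL", widthUm = 450, heightUm = 450,
                                   nDucts = 9L, nucleusDiameterMean = 7,
                                   nucleusDiameterSd = 1, seed = 7))
  d <- sceneNuclei(s)$majorAxis
  expect_gte(length(d), 100)
  expect_lt(abs(mean(d) - 7), 0.3)
  expect_lt(abs(sd(d) - 1), 0.3)
})

test_that("scene invariants hold: mask geometry, nucleus centres, collagen support", {
  for (lab in c("NORMAL", "CANCER")) {
    s <- generateScene(PhantomParams(lab, seed = 21,
                                     membraneLossFraction = 0.5,
                                     fibrosisFraction = 0.2))
    expect_true(validObject(s))  # validity enforces all three invariants
    idx <- cbind(floor(s@nuclei$centerY / s@pixelSize) + 1L,
                 floor(s@nuclei$centerX / s@pixelSize) + 1L)
    expect_true(all(s@epitheliumMask[idx]))
    off <- !(s@membraneMask | s@fibrosisMask)
    expect_true(all(s@collagenDensity[off] == 0))
  }
})

test_that("a raster too small to hold one duct is an error", {
  expect_error(generateScene(PhantomParams("NORMAL", widthUm = 15,
                                           heightUm = 15, nDucts = 1L)),
               "too small")
})

test_that("rendered stacks are deterministic and obey the intensity contract", {
  s <- smallNormalScene(seed = 2)
  st1 <- renderSpectral(s, 820, seed = 77)
  st2 <- renderSpectral(s, 820, seed = 77)
  expect_identical(st1@data, st2@data)
  expect_true(all(st1@data >= 0 & st1@data <= 4095))
  st3 <- renderSpectral(s, 820, seed = 78)
  expect_false(identical(st1@data, st3@data))
})

test_that("expected emission is linear in the amplitudes before clipping", {
  s <- smallNormalScene(seed = 3)
  a1 <- defaultAmplitudes()
  a2 <- lapply(a1, function(x) 2 * x)
  e1 <- expectedSpectral(s, 820, a1)
  e2 <- expectedSpectral(s, 820, a2)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
})

test_that("SHG signal scales quadratically with collagen density", {
  densities <- c(0.25, 0.5, 0.75, 1.0)
  signal <- vapply(densities, function(d) {
    s <- generateScene(PhantomParams("NORMAL", widthUm = 120, heightUm = 120,
                                     nDucts = 1L, immuneDensity = 0, seed = 4,
                                     membraneCollagenDensity = d))
    e <- expectedSpectral(s, 820, modifyList(defaultAmplitudes(),
                                             list(background = 0)))
    shgBin <- e[, , 2]  # the 410-420 nm bin
    mean(shgBin[s@membraneMask])
  }, numeric(1))
  ratios <- signal / signal[length(signal)]
  expect_equal(ratios, densities^2, tolerance = 0.01)
  # the headline contrast: halving density quarters the signal
  expect_equal(signal[4] / signal[2], 4.0, tolerance = 0.01)
})

test_that("no collagen means no excess signal in the half-wavelength bin", {
  s <- generateScene(PhantomParams("NORMAL", widthUm = 120, heightUm = 120,
                                   nDucts = 1L, membraneCollagenDensity = 0,
                                   seed = 6))
  st <- renderSpectral(s, 820, seed = 1)
  m1 <- mean(st@data[, , 2])  # 410-420 nm
  m2 <- mean(st@data[, , 3])  # 420-430 nm
  expect_lt(abs(m1 - m2) / max(m2, 1), 0.1)
})

test_that("an empty scene renders to an all-zero noise-free stack", {
  s <- smallNormalScene(seed = 8)
  amp0 <- lapply(defaultAmplitudes(), function(x) 0)
  st <- renderSpectral(s, 820, noise = FALSE, amplitudes = amp0)
  expect_true(all(st@data == 0L))
})

test_that("filter channels isolate the tissue components", {
  amps <- defaultAmplitudes()
  zero <- lapply(amps, function(x) 0)
  channelMeans <- function(scene, keep) {
    a <- modifyList(zero, amps[keep])
    im <- renderFilters(scene, noise = FALSE, amplitudes = a)
    masked <- scene@membraneMask | scene@epitheliumMask | scene@immuneMask
    vapply(1:3, function(k) mean(im@data[, , k][masked]), numeric(1))
  }
  sN <- smallNormalScene(seed = 10)
  # membrane fibres only: SHG at 390 nm lands in the 417/60 band and nowhere else
  v <- channelMeans(sN, "shg")
  expect_gt(v[1], 0)
  expect_equal(v[2], 0)
  expect_equal(v[3], 0)
  # epithelium only: blue and green, ~zero red
  v <- channelMeans(sN, c("nadph", "fadEpi"))
  expect_gt(v[1], 0.1 * max(v))
  expect_gt(v[2], 0.1 * max(v))
  expect_lt(v[3], 0.05 * max(v))
  # immune cells only: green and red, ~zero blue
  sI <- generateScene(PhantomParams("NORMAL", widthUm = 120, heightUm = 120,
                                    nDucts = 1L, immuneDensity = 3, seed = 10))
  v <- channelMeans(sI, c("fadImmune", "lipofuscin"))
  expect_gt(v[2], 0.1 * max(v))
  expect_gt(v[3], 0.1 * max(v))
  expect_lt(v[1], 0.1 * max(v))
})
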
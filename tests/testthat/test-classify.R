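test_that("ROI placement is pre-registered, deterministic and non-overlapping", {
  r1 <- placeROIs(600, 600, 100, 5, seed = 7)
  r2 <- placeROIs(600, 600, 100, 5, seed = 7)
  expect_equal(length(r1), 5L)
  expect_identical(lapply(r1, function(r) c(r@originX, r@originY)),
                   lapply(r2, function(r) c(r@originX, r@originY)))
  # pairwise overlap area is zero
  for (i in seq_along(r1)) for (j in seq_along(r1)) if (i < j) {
    a <- r1[[i]]; b <- r1[[j]]
    ox <- max(0, min(a@originX + 100, b@originX + 100) - max(a@originX, b@originX))
    oy <- max(0, min(a@originY + 100, b@originY + 100) - max(a@originY, b@originY))
    expect_equal(ox * oy, 0)
  }
  # a different seed shuffles placement
  r3 <- placeROIs(600, 600, 100, 5, seed = 8)
  expect_false(identical(lapply(r1, function(r) c(r@originX, r@originY)),
                         lapply(r3, function(r) c(r@originX, r@originY))))
})

test_that("ROI placement packs as many as fit, warning when short", {
  expect_warning(r <- placeROIs(120, 120, 100, 5, seed = 1), "only 1")
  expect_equal(length(r), 1L)
  expect_error(placeROIs(80, 80, 100, 1), "too small")
})

test_that("the threshold rule matches the published operating point", {
  th <- thresholds()  # N <= 9.5, S > 3.1
  expect_equal(classifyArea(7.0, 5.0, th), "NORMAL")
  expect_equal(classifyArea(9.5, 3.1, th), "CANCER")   # S not strictly greater
  expect_equal(classifyArea(9.5, 3.1000001, th), "NORMAL")  # N inclusive
  expect_equal(classifyArea(12.0, 1.2, th), "CANCER")
  expect_equal(classifyArea(NA, 4.0, th), "OMITTED")
})

test_that("threshold monotonicity: tightening moves areas only toward cancer", {
  set.seed(5)
  cases <- data.frame(n = runif(200, 4, 15), s = runif(200, 0.5, 8))
  base <- mapply(classifyArea, cases$n, cases$s,
                 MoreArgs = list(th = thresholds()))
  higherS <- mapply(classifyArea, cases$n, cases$s,
                    MoreArgs = list(th = thresholds(sMin = 4.5)))
  lowerN <- mapply(classifyArea, cases$n, cases$s,
                   MoreArgs = list(th = thresholds(nMax = 8)))
  expect_true(all(higherS[base == "CANCER"] == "CANCER"))
  expect_true(all(lowerN[base == "CANCER"] == "CANCER"))
})

test_that("confusion counts non-omitted areas with cancer positive", {
  res <- data.frame(
    predicted = c(rep("NORMAL", 54), rep("CANCER", 10),
                  rep("CANCER", 77), rep("NORMAL", 3), "OMITTED"),
    truth = c(rep("NORMAL", 64), rep("CANCER", 80), "NORMAL"))
  cm <- confusion(res)
  expect_equal(c(cm@tp, cm@fn, cm@tn, cm@fp), c(77L, 3L, 54L, 10L))

  empty <- confusion(data.frame(predicted = character(0), truth = character(0)))
  expect_equal(c(empty@tp, empty@fp, empty@tn, empty@fn), rep(0L, 4))

  perfect <- data.frame(predicted = c("CANCER", "NORMAL"),
                        truth = c("CANCER", "NORMAL"))
  cmp <- confusion(perfect)
  expect_equal(c(cmp@fp, cmp@fn), c(0L, 0L))
})

test_that("metrics reproduce their defining ratios and flag zero denominators", {
  m <- metrics(confusionMatrix(tp = 77, fp = 10, tn = 54, fn = 3))
  expect_equal(m$sensitivity, 77 / 80)
  expect_equal(m$specificity, 54 / 64)
  expect_equal(m$ppv, 77 / 87)
  expect_equal(m$npv, 54 / 57)
  expect_equal(m$kappa, bruteForceKappa(77, 10, 54, 3), tolerance = 1e-12)

  # all-cancer predictions leave specificity's complement metrics defined
  # but NPV undefined (tn + fn = 0)
  m2 <- metrics(confusionMatrix(tp = 5, fp = 5, tn = 0, fn = 0))
  expect_true(is.na(m2$npv))
  expect_true("npv" %in% m2$undefined)
  expect_false(is.na(m2$ppv))

  # chance-level agreement has kappa exactly zero
  expect_equal(metrics(confusionMatrix(25, 25, 25, 25))$kappa, 0)
})

test_that("kappa agrees with independent oracles on random 2x2 tables", {
  set.seed(1234)
  for (i in 1:1000) {
    cc <- as.integer(sample(0:60, 4, replace = TRUE))
    if (sum(cc) == 0) cc <- cc + 1L
    k <- metrics(confusionMatrix(cc[1], cc[2], cc[3], cc[4]))$kappa
    kb <- bruteForceKappa(cc[1], cc[2], cc[3], cc[4])
    if (is.na(kb) || !is.finite(kb)) {
      expect_true(is.na(k) || !is.finite(k))
    } else {
      expect_equal(k, kb, tolerance = 1e-12)
    }
  }
  # spot-check against a third-party implementation
  skip_if_not_installed("e1071")
  tab <- matrix(c(77, 10, 3, 54), 2)
  expect_equal(metrics(confusionMatrix(77, 10, 54, 3))$kappa,
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
})

test_that("classifyArea is pure: batch order cannot matter", {
  set.seed(3)
  n <- runif(50, 4, 14); s <- runif(50, 0.5, 8)
  fwd <- mapply(classifyArea, n, s)
  perm <- sample(50)
  bwd <- mapply(classifyArea, n[perm], s[perm])
  expect_identical(fwd[perm], bwd)
})

test_that("the pipeline composes indices, rule and tallies on one case", {
  res <- analyzeCase("clean", "NORMAL", seed = 201,
                     widthUm = 200, heightUm = 200,
                     roiCount = 4, imageId = "n1")
  expect_equal(nrow(res$results), 4L)
  expect_true(all(res$results$predicted %in% c("NORMAL", "CANCER", "OMITTED")))
  # every evaluated area carries both indices and the winning subwindow
  ok <- res$results$predicted != "OMITTED"
  expect_true(all(is.finite(res$results$indexS)))
  expect_true(all(is.finite(res$results$indexN[ok])))
  expect_true(all(res$results$subwindowX >= res$results$roiX))
  # clean normal tissue: intact membrane, small nuclei
  expect_true(all(res$results$predicted[ok] == "NORMAL"))
  expect_error(runPipeline(res$results, NULL, "NORMAL"), "820 nm")
})

test_that("end-to-end accuracy degrades as the class contrast shrinks to zero", {
  accuracyAt <- function(meanDiam, collagen, seed) {
    r <- analyzeCase("clean", "CANCER", seed = seed,
                     widthUm = 200, heightUm = 200, roiCount = 4,
                     nucleusDiameterMean = meanDiam, nucleusDiameterSd = 1,
                     membraneLossFraction = 1 - collagen)$results
    ok <- r$predicted != "OMITTED"
    if (!any(ok)) return(NA)
    mean(r$predicted[ok] == r$truth[ok])
  }
  # full contrast vs no contrast (a "cancer" scene built like normal tissue)
  accFull <- accuracyAt(12, 0, seed = 301)
  accNone <- accuracyAt(7, 1, seed = 301)
  expect_gte(accFull, accNone)
  expect_equal(accFull, 1)
  expect_equal(accNone, 0)  # indistinguishable from normal by construction
})
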
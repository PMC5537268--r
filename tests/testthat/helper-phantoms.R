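# Shared fixtures: small scenes built in code so tests stay fast.

# A compact normal scene (one duct, no immune cells) for morphometry tests.
smallNormalScene <- function(seed = 11, ...) {
  generateScene(PhantomParams("NORMAL", widthUm = 120, heightUm = 120,
                              nDucts = 1L, immuneDensity = 0, seed = seed, ...))
}

smallCancerScene <- function(seed = 12, ...) {
  generateScene(PhantomParams("CANCER", widthUm = 120, heightUm = 120,
                              nDucts = 1L, immuneDensity = 0, seed = seed, ...))
}

# Build a SpectralStack directly from an array (bypassing the renderer).
stackFromArray <- function(arr, excitation = 820, pixelSize = 0.5) {
  storage.mode(arr) <- "integer"
  new("SpectralStack", data = arr, excitation = excitation,
      binEdges = seq(400, 650, by = 10), pixelSize = pixelSize)
}

# Stack with the same 25-bin spectrum at every pixel.
uniformStack <- function(spectrum, nr = 40, nc = 40, ...) {
  arr <- array(0L, c(nr, nc, 25))
  for (k in 1:25) arr[, , k] <- as.integer(spectrum[k])
  stackFromArray(arr, ...)
}

# Greedy centroid matching of detections to planted nuclei (<= tol um).
matchNuclei <- function(detected, planted, tol = 2) {
  if (!nrow(detected)) return(integer(0))
  vapply(seq_len(nrow(detected)), function(i) {
    d2 <- (planted$centerX - detected$centroidX[i])^2 +
          (planted$centerY - detected$centroidY[i])^2
    j <- which.min(d2)
    if (d2[j] <= tol^2) j else NA_integer_
  }, integer(1))
}

# Independent brute-force Cohen's kappa from the 2x2 margins.
bruteForceKappa <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  po <- (tp + tn) / n
  rowCancer <- tp + fp; rowNormal <- fn + tn   # predicted margins
  colCancer <- tp + fn; colNormal <- fp + tn   # truth margins
  pe <- (rowCancer * colCancer + rowNormal * colNormal) / n^2
  (po - pe) / (1 - pe)
}
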
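#' Simulate one imaging case
#'
#' Generates a ground-truth scene from a named preset and renders both
#' acquisition modes: the three-filter image at 780 nm (morphometry input)
#' and the 25-bin spectral stack at 820 nm (index S input).  Optionally
#' writes the three artefacts to a directory (\code{filter.tiff},
#' \code{spectral820.tiff} with JSON sidecars, \code{scene.json}).
#'
#' @param preset phantom preset name, see \code{\link{phantomPreset}}.
#' @param label tissue class, \code{NULL} for the preset default.
#' @param seed integer seed driving scene geometry and both noise draws.
#' @param outDir optional output directory.
#' @param ... overrides passed to \code{\link{phantomPreset}}.
#' @return list with \code{scene}, \code{filterImage}, \code{spectral820}.
#' @export
simulateCase <- function(preset = "clean", label = NULL, seed = 1L,
                         outDir = NULL, ...) {
  params <- phantomPreset(preset, label = label, seed = seed, ...)
  scene <- generateScene(params)
  filt <- renderFilters(scene, gain = params@photonGain,
                        readNoiseSd = params@readNoiseSd, seed = seed)
  spec <- renderSpectral(scene, 820, gain = params@photonGain,
                         readNoiseSd = params@readNoiseSd, seed = seed + 1L)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeStack(filt, file.path(outDir, "filter.tiff"))
    writeStack(spec, file.path(outDir, "spectral820.tiff"))
    writeScene(scene, file.path(outDir, "scene.json"))
  }
  list(scene = scene, filterImage = filt, spectral820 = spec)
}

#' Simulate and classify one case end-to-end
#'
#' @inheritParams simulateCase
#' @param th thresholds, see \code{\link{thresholds}}.
#' @param roiSide,roiCount ROI configuration.
#' @param imageId identifier recorded in the results table.
#' @return the \code{\link{runPipeline}} result, plus the \code{scene}.
#' @export
analyzeCase <- function(preset = "clean", label = NULL, seed = 1L,
                        th = thresholds(), roiSide = 100, roiCount = 5,
                        imageId = paste0(preset, "-", seed), ...) {
  case <- simulateCase(preset, label = label, seed = seed, ...)
  out <- runPipeline(case$filterImage, case$spectral820,
                     truth = sceneLabel(case$scene), th = th,
                     roiSide = roiSide, roiCount = roiCount,
                     roiSeed = seed, imageId = imageId)
  out$scene <- case$scene
  out
}

#' Diagnostic metrics recomputed from the bundled reference counts
#'
#' Recomputes, from the printed counts of the original clinical evaluation
#' (bundled at \code{inst/extdata/reference_counts.json}), the two-index
#' classifier's confusion matrix and diagnostic statistics, the pathologists'
#' perfect-agreement reading, and the descriptive fractions.
#'
#' @return list with \code{classifier} (confusion matrix and metrics),
#'   \code{pathologists} (metrics of the reading study), and
#'   \code{fractions} (percentages recomputed from printed counts).
#' @export
referenceMetrics <- function() {
  path <- system.file("extdata", "reference_counts.json", package = "nlmpm",
                      mustWork = TRUE)
  rc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tw <- rc$two_index_classifier
  cmC <- confusionMatrix(
    tp = tw$cancer_areas_classified_cancer,
    fn = tw$cancer_areas_total - tw$cancer_areas_classified_cancer,
    tn = tw$normal_areas_classified_normal,
    fp = tw$normal_areas_total - tw$normal_areas_classified_normal)
  pa <- rc$pathologist_reading
  cmP <- confusionMatrix(
    tp = pa$cancer_cases_called_cancer,
    fn = pa$cancer_cases_total - pa$cancer_cases_called_cancer,
    tn = pa$normal_cases_called_normal,
    fp = pa$normal_cases_total - pa$normal_cases_called_normal)
  sh <- rc$shg_loss
  list(
    classifier = list(confusion = cmC, metrics = metrics(cmC)),
    pathologists = list(confusion = cmP, metrics = metrics(cmP)),
    fractions = list(
      normalClassifiedNormalPct =
        round(100 * tw$normal_areas_classified_normal / tw$normal_areas_total),
      cancerTwoIndexPatternPct =
        round(100 * tw$cancer_areas_two_index_pattern / tw$cancer_areas_total),
      shgDiminishedPct =
        round(100 * sh$cancer_patients_with_diminished_shg /
                sh$cancer_patients_total)))
}
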
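#' Built-in endogenous fluorophore models
#'
#' Returns the emitter library used by the phantom renderer.  The models
#' encode the emission signatures of colorectal mucosa under two-photon
#' excitation:
#' \itemize{
#'   \item \strong{NADPH} — reduced pyridine nucleotides of epithelial
#'     cytoplasm: Gaussian emission peaking near 460 nm, efficiently excited
#'     at 730 nm and barely at 820/900 nm.
#'   \item \strong{FAD} — flavin adenine dinucleotide of immune cells (and a
#'     minor epithelial component): Gaussian emission peaking near 530 nm,
#'     excitable across all wavelengths.
#'   \item \strong{LIPOFUSCIN} — aggregated undigested material in immune
#'     cells: broad uniform emission across 450-650 nm, overlapping FAD, which
#'     is what puts immune cells in the red detection channel.
#'   \item \strong{BACKGROUND} — weak broadband tissue autofluorescence /
#'     scatter spanning the whole detection range; keeps dark regions off
#'     zero so band ratios stay finite.
#'   \item \strong{SHG} — second-harmonic generation by aligned collagen:
#'     coherent emission concentrated at exactly half the excitation
#'     wavelength (no Gaussian parameters), present under 780/820/900 nm;
#'     under 730 nm the harmonic at 365 nm falls below the detection range.
#' }
#'
#' Excitation efficiencies are relative, in [0,1], with 1 at the emitter's
#' reference excitation.
#'
#' @return Named list of \linkS4class{FluorophoreModel} objects.
#' @examples
#' fl <- fluorophoreLibrary()
#' fluorophoreEmission(fl$NADPH, 730)
#' @export
fluorophoreLibrary <- function() {
  eff <- function(...) {
    v <- c(...)
    names(v) <- as.character(SUPPORTED_EXCITATIONS)
    v
  }
  list(
    NADPH = new("FluorophoreModel", name = "NADPH", kind = "gaussian",
                peakCenter = 465, peakWidthSigma = 35,
                excitationEfficiency = eff(1.0, 0.6, 0.08, 0.02)),
    FAD = new("FluorophoreModel", name = "FAD", kind = "gaussian",
              peakCenter = 535, peakWidthSigma = 40,
              excitationEfficiency = eff(0.7, 0.9, 1.0, 0.8)),
    LIPOFUSCIN = new("FluorophoreModel", name = "LIPOFUSCIN", kind = "uniform",
                     rangeLo = 450, rangeHi = 650,
                     excitationEfficiency = eff(0.8, 0.9, 1.0, 0.9)),
    BACKGROUND = new("FluorophoreModel", name = "BACKGROUND", kind = "uniform",
                     rangeLo = 400, rangeHi = 650,
                     excitationEfficiency = eff(1.0, 1.0, 1.0, 1.0)),
    SHG = new("FluorophoreModel", name = "SHG", kind = "shg",
              excitationEfficiency = eff(1.0, 1.0, 1.0, 1.0))
  )
}

## Emission mass of a model between wavelengths lo and hi (nm) at a given
## excitation, in units of the model's unit-normalised total emission.
## Gaussian emitters use the unit-area Gaussian pdf; uniform emitters spread
## unit mass over their support; SHG places unit mass at excitation/2.
fluorophoreBandMass <- function(model, excitation, lo, hi) {
  key <- as.character(excitation)
  if (!key %in% names(model@excitationEfficiency))
    stop("unsupported excitation wavelength: ", excitation,
         " nm (supported: ", paste(SUPPORTED_EXCITATIONS, collapse = ", "), ")")
  eff <- model@excitationEfficiency[[key]]
  mass <- switch(model@kind,
    gaussian = pnorm(hi, model@peakCenter, model@peakWidthSigma) -
               pnorm(lo, model@peakCenter, model@peakWidthSigma),
    uniform = {
      ov <- pmax(0, pmin(hi, model@rangeHi) - pmax(lo, model@rangeLo))
      ov / (model@rangeHi - model@rangeLo)
    },
    shg = as.numeric(excitation / 2 >= lo & excitation / 2 < hi)
  )
  eff * mass
}

#' Per-bin relative emission of a fluorophore model
#'
#' Integrates the model's unit-normalised emission profile over each
#' wavelength bin and scales by the relative excitation efficiency at the
#' requested excitation wavelength, so the spectrum sums to
#' \code{efficiency(excitation)} times the emission mass falling inside the
#' detection range.  SHG returns all its mass in the single bin containing
#' half the excitation wavelength, and an all-zero spectrum when the harmonic
#' falls below the first bin edge.
#'
#' @param model A \linkS4class{FluorophoreModel}.
#' @param excitation Excitation wavelength (nm); must be one of 730, 780,
#'   820, 900 — no silent interpolation.
#' @param binEdges Ascending bin-edge wavelengths (nm); default the 25-bin
#'   400-650 nm detection grid.
#' @return Numeric vector of per-bin relative emission, length
#'   \code{length(binEdges) - 1}.
#' @examples
#' fl <- fluorophoreLibrary()
#' which.max(fluorophoreEmission(fl$NADPH, 730))  # the 460-470 nm bin
#' fluorophoreEmission(fl$SHG, 820)               # mass only at 410-420 nm
#' @export
fluorophoreEmission <- function(model, excitation,
                                binEdges = SPECTRAL_BIN_EDGES) {
  stopifnot(is(model, "FluorophoreModel"))
  if (!excitation %in% SUPPORTED_EXCITATIONS)
    stop("unsupported excitation wavelength: ", excitation,
         " nm (supported: ", paste(SUPPORTED_EXCITATIONS, collapse = ", "), ")")
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("binEdges must be strictly ascending")
  n <- length(binEdges) - 1L
  fluorophoreBandMass(model, excitation, binEdges[seq_len(n)], binEdges[-1L])
}
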
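Package: nlmpm
Title: Label-Free Multiphoton Microscopy Phantoms and Two-Index
    Classification of Colorectal Mucosa
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates label-free multiphoton excitation microscopy (NL-MPM)
    images of colorectal mucosa with full ground truth, and implements the
    two-index diagnostic analysis used to discriminate normal from cancerous
    tissue: index N, the mean major-axis diameter of nuclear signal-void
    regions inside fluorescent epithelium, and index S, the second-harmonic
    generation (SHG) band ratio of emission at 410-420 nm to 420-430 nm under
    820 nm excitation. Provides a synthetic phantom generator (endogenous
    fluorophore emission models for NAD(P)H, FAD, lipofuscin and collagen SHG;
    duct geometry; noise and blur), region-of-interest spectral extraction,
    signal-void nuclear morphometry, threshold classification, and diagnostic
    accuracy statistics including Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Classification
RoxygenNote: 7.3.3
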
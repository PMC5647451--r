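Package: seqpixe
Title: Sequential PIXE/PIGE Quantification of Mineral Loss and Fluorine
    Uptake in Root Dentin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibrated conversion of proton-beam line-scan yields (Ca K-alpha
    X-rays via PIXE, fluorine gamma rays via PIGE) into concentration-depth
    profiles of root dentin, copper-fiducial superimposition of scans taken
    before and after demineralization, 5/95 percent lesion-boundary detection,
    and integral lesion metrics (Ca loss, F uptake, F penetration depth, and
    the micro-CT mineral-loss analogue), together with exact small-sample
    Mann-Whitney and Spearman cohort statistics.  A synthetic-specimen
    generator with Poisson counting noise emulates paired treated/control
    root-dentin scans so the whole pipeline is testable without instrument
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
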
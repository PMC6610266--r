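Package: xelobe
Title: Lobar Lung Ventilation Analysis for Time-Series Hyperpolarized-Gas MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lobar lung function from multi-modality chest imaging
    of chronic obstructive pulmonary disease. Implements the non-renewable
    magnetization signal model for hyperpolarized xenon-129 MRI breath-hold
    time series, nonlinear least-squares estimation of flip angle and T1 with
    an identifiability diagnostic, decay-corrected ventilation maps, lobar
    scoring (CT percent-emphysema below -950 HU, relative and absolute
    percent-ventilation, SPECT lobar ventilation/perfusion shares), and
    cohort comparison statistics (Pearson correlation with Fisher-z intervals,
    ordinary least-squares regression). A five-lobe digital thorax phantom
    generates CT-like, xenon-MRI-like and SPECT-like volumes with known
    ground truth so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
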
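Package: geciq
Title: Quantification of Genetically Encoded Calcium Indicator Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for characterizing genetically encoded calcium indicators
    (GECIs) and for benchmarking soma-targeted sensor variants in population
    imaging. Implements Hill-equation fitting of calcium titrations, pH
    titrations and photobleaching curves; EGTA calibration-buffer arithmetic;
    simulation of spike trains, calcium transients, indicator fluorescence and
    noisy imaging movies with full ground truth; baseline estimation and
    delta-F-over-F metrics (peak amplitude, SNR, half-rise and decay times,
    responsiveness classifiers, orientation selectivity); ROI-level spatial
    quantification (neuropil annulus and subtraction, neurite expression
    decay, intersection-over-union matching, labeling density); and
    distance-binned pairwise correlation analysis of neuropil contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
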
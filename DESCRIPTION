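Package: bhcvr
Title: Breath-Hold Cerebrovascular Reactivity Mapping from Multi-Weighting fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for mapping cerebrovascular reactivity (CVR) from
    breath-hold hypercapnia fMRI acquired with interleaved tag/control
    multi-weighting sequences (short-TE ASL, gradient-echo BOLD, spin-echo
    BOLD). Extracts an end-tidal CO2 (PetCO2) regressor from raw expired-CO2
    capnography, separates perfusion and BOLD signals by surround
    subtraction/averaging, estimates voxelwise CVR, confidence z-scores and
    hemodynamic lag by lagged linear regression, and reproduces group-level
    comparisons: gray-matter summaries under ASL-confidence thresholding,
    across-subject and bootstrap spatial correlations, per-ROI Fisher-z maps
    with venous-density stratification, second-level t-maps and coefficients
    of variation. Includes a synthetic-data generator emulating the
    breath-hold protocol with known ground truth, so every stage is testable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
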
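Package: ocureliab
Title: Split-Half Reliability of Oculomotor Capture and Fixation-Time
    Measures in Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Permutation-based split-half reliability analysis for
    trial-level eye-tracking visual-search data.  Trials are randomly
    split into two halves balanced per condition per run, per-subject
    difference scores (oculomotor capture probability or target
    fixation time between a critical and a baseline distractor
    condition) are computed on each half and Pearson-correlated, and
    the procedure is repeated many times to estimate internal
    consistency.  Includes the Spearman-Brown correction, Fisher-z
    confidence intervals, z-score outlier screening, a non-parametric
    randomization test for comparing reliability between two measures
    or groups, a tidy CSV interchange format for scored trials, and a
    synthetic trial generator with known ground-truth reliability for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
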
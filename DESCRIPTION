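Package: cprnfl
Title: Simulation and Evaluation of Global Circumpapillary RNFL Thickness
    Change in Glaucoma Progression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the change in global (360-degree average)
    circumpapillary retinal nerve fiber layer thickness (the G metric and
    its change, delta-G) as an event criterion for glaucomatous
    progression on optical coherence tomography circle scans. Provides a
    synthetic paired-visit profile generator with known ground truth
    (local and widespread lesions, segmentation, clipping, scaling and
    rotation artifacts, calibrated test-retest noise), profile metrics
    and a region-wise decomposition of delta-G, fixed-cutoff and
    quantile-regression progression criteria, rule-based grading of
    defects and scan artifacts, and confusion-matrix evaluation of
    criteria against reference labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
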
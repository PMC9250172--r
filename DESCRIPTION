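Package: srsdosim
Title: Dosimetric Evaluation of Single-Isocenter Multi-Target Radiosurgery Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating stereotactic radiosurgery (SRS) plans for
    multiple brain metastases on voxel dose grids: dose-volume histograms,
    Paddick conformity index, gradient index, healthy-brain dose metrics
    (V5-V12Gy, mean dose) with per-lesion 12 Gy cluster decomposition, a
    clinical plan-acceptance policy, and paired cohort comparison with the
    exact Wilcoxon signed-rank test. Includes a synthetic cohort generator
    producing paired multi-target plans with analytically controlled dose
    falloff, so the full pipeline is testable against closed-form oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
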
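Package: lesionmap
Title: Voxel-Based Lesion-Symptom Mapping and Stretch-Reflex Threshold Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating focal brain damage to behavioral deficits after
    stroke. Implements voxel-based lesion-symptom mapping (VLSM) with a
    tie-corrected Mann-Whitney voxel statistic, Benjamini-Hochberg false
    discovery rate control, cluster-based reporting against an atlas
    parcellation, and conjunction analysis of two symptom maps into shared and
    selective voxel sets. Also estimates the tonic stretch reflex threshold
    (TSRT), a biomechanical measure of spasticity, from passive-stretch trials
    by detecting reflex EMG onset and extrapolating dynamic angle-velocity
    thresholds to zero velocity. A seeded synthetic-cohort generator produces
    lesion masks, behavioral scores and stretch trials with planted ground
    truth so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
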
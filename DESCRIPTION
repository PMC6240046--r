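Package: tmrnet
Title: Beta-Series Network Analysis of Cued Memory Reactivation During Sleep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-wise (beta-series) functional connectivity analysis of
    targeted memory reactivation experiments, in which auditory cues are
    played during slow-wave sleep to bias consolidation of recently learned
    object-location associations. Provides a protocol-faithful synthetic
    data generator with planted ground truth (modular beta-amplitude
    correlation structure, a condition-specific rise in one parcel's
    inter-modular coupling, and a brain-behavior association with overnight
    forgetting), trial-wise GLM estimation with AR(1) prewhitening,
    FDR-thresholded connectivity graphs, two-scale Louvain community
    detection with voxel-level participation-coefficient mapping,
    seed-based connectivity contrasts, paired and covariate group
    inference with permutation cluster-extent correction and small-volume
    FDR correction across regions of interest, and the behavioral
    statistics (placement error, overnight forgetting, Kendall tau-b,
    Williams-Hotelling comparison of dependent correlations) linking
    network integration to memory stabilization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
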
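Package: microsurv
Title: Morphometry and Surveillance Dynamics of Microglia from Two-Photon Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantifying microglial morphology and process
    surveillance dynamics from two-channel (vessel + microglia) two-photon time-lapse
    recordings. Provides vessel-referenced translation registration, temporal averaging
    and maximum-intensity projection, skeleton-based per-cell morphometry (soma area,
    territory area, primary and total process length), process-tip tracking with
    surveillance-territory and extension/retraction speed statistics, resolution
    estimation by full width at half maximum, and a group-comparison decision tree
    (Welch/Mann-Whitney, ANOVA/Kruskal-Wallis with Bonferroni-corrected post hoc tests).
    A synthetic two-channel time-lapse generator with condition presets (control,
    diabetic, liraglutide-treated, LPS) and exported ground truth drives validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    data.table,
    e1071,
    grDevices,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
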
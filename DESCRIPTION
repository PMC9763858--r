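Package: patchstoich
Title: Single-Molecule Stoichiometry and Spatial Clustering of Membrane
    Receptor Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule fluorescence imaging of
    membrane receptor assemblies. Detects diffraction-limited foci in
    Slimfield/PaTCH image stacks with iterative Gaussian-mask sub-pixel
    localization, links foci into tracks by disk-overlap and intensity-ratio
    gates, calibrates the unitary fluorophore brightness from post-bleach
    modal intensities and Chung-Kennedy photobleaching step intervals, and
    estimates molecular stoichiometries and their dimer periodicity from
    kernel density estimates. Quantifies spatial clustering of
    super-resolution puncta with Ripley's K/L/H statistics, global plus
    local Otsu binarization and object analysis, with simulated
    complete-spatial-randomness controls. Includes a synthetic-data
    generator with known ground truth for every stage, and the
    Brunner-Munzel nonparametric two-sample test with Bonferroni-adjusted
    significance levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    spatial
Config/testthat/edition: 3
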
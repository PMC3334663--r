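Package: bonemorph
Title: Subchondral Bone Morphometry from Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of subchondral bone architecture in small-animal
    micro-computed tomography, built for longitudinal paired-limb studies of
    experimental osteoarthritis. Provides uniform-threshold segmentation,
    stacked-ROI volumes of interest, direct three-dimensional trabecular
    morphometry (BV, BV/TV, Tb.Th, Tb.Sp via maximal-sphere local thickness,
    Tb.N), subchondral plate separation with thickness and porosity,
    synthetic phantom generators with known ground truth, cohort simulation,
    and the paired repeated-measures inferential recipe (two-way
    repeated-measures ANOVA, paired t tests, Holm stepdown adjustment) with
    publication-style summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
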
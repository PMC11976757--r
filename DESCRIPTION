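Package: cvrsteal
Title: Cerebrovascular Reactivity Mapping and Steal-Phenomenon Volumetrics
    from Hypercapnic BOLD fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxelwise cerebrovascular reactivity (CVR) mapping from BOLD
    fMRI acquired under a step end-tidal CO2 challenge, with quality-control
    gates on head motion (framewise displacement) and stimulus adequacy,
    atlas-referenced Z-scoring, classification of vascular steal voxels
    (paradoxical negative reactivity), overlap volumetrics against diffusion
    lesion masks, and a cohort statistics stage (quantiles, partial Spearman
    rank correlation, proportional-odds ordinal regression with a Brant-Wald
    proportional-odds check). Includes a synthetic phantom and cohort
    generator with known ground truth so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    MASS,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
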
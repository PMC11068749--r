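Package: condylovol
Title: Longitudinal CBCT Volumetry of the Mandibular Condyle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies longitudinal bone change of the mandibular condyle in
    temporomandibular joint osteoarthritis from paired cone-beam CT scans.
    Bone is segmented by maximum-entropy (Kapur) thresholding with the
    pre-treatment threshold reused at follow-up, the mandibles are aligned by
    rigid intensity-based registration, a common condylar-head volume of
    interest is cropped on the pre-treatment grid, and the change is
    decomposed by voxel overlap into total difference (dV), net resorption
    (dV-) and net deposition (dV+), with a condylar-neck/ramus validation
    region quantifying residual segmentation/registration error. Includes
    truth-labelled synthetic condyle phantoms and cohort tables for
    validation, and the nonparametric cohort statistics (Mann-Whitney,
    Kruskal-Wallis, Spearman, multiple linear regression) of the staged
    erosion/pain analysis plan.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
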
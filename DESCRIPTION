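Package: cinefunc
Title: Cardiac Function and Segmentation Agreement from Short-Axis Cine Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of left-ventricular function and segmentation
    agreement from short-axis cine image stacks. Generates synthetic cine
    phantoms with ground-truth masks and analytic volumes, trains a compact
    encoder-decoder segmentation network with a two-step frozen/unfrozen
    transfer-learning schedule, converts between label masks and
    epicardial/endocardial contours (with a documented plain-text contour file
    dialect), computes EDV, ESV, SV, EF and LV mass by voxel counting, and
    quantifies observer and model agreement with Dice scores, Hausdorff
    distances, Bland-Altman limits, intraclass correlation, coefficients of
    variability and paired t-tests with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
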
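Package: polarisc
Title: Inter-Subject Correlation Analysis of Neural Polarization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying neural polarization with naturalistic-stimulus
    fMRI: voxel-wise one-to-average and within- versus between-group
    inter-subject correlation (ISC), sign-flip permutation inference with
    two-stage Benjamini-Krieger-Yekutieli false discovery rate control, peak
    extraction and peak-level statistics, Likert attitude scoring with a
    median-split group assignment, and a synthetic-cohort generator that
    emulates the statistical structure of a two-group listening study so the
    whole pipeline can be exercised without access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
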
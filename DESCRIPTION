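Package: mcdetect
Title: Self-Learning Bayesian Detection of Clustered Microcalcifications
    in Digital Mammograms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Single-stage detection of clustered microcalcifications (MCs)
    in digital mammograms using a Gaussian Bayesian pixel classifier whose
    MC-class training samples are synthesized on the fly: a binary standard
    model of disc-shaped calcifications is blended into the input mammogram
    under a modeling constant K, and the blended pixels train the MC class
    while two background regions train the healthy-tissue class. Each pixel
    is described by a four-channel feature stack (graylevel, local-maximum
    rank, db4 wavelet highpass reconstruction, and the ED8 point-singularity
    measure). Includes Otsu-based breast masking, a physiology-aware cluster
    filter, block-based sensitivity/specificity evaluation, and a synthetic
    mammogram phantom generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Software, Classification, Segmentation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
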
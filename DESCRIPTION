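Package: widowseg
Title: Multilevel Image Thresholding with an Improved Black Widow
    Optimization Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multilevel grayscale image thresholding driven by the Black
    Widow Optimization Algorithm (BWOA) and its improved variant (IBWOA)
    that augments procreation with Levy-flight steps and adds
    quasi-opposition-based learning.  Thresholds are selected by
    maximizing Otsu's between-class variance or Kapur's entropy over the
    image histogram.  Includes an exhaustive-search oracle for exact
    optima at small threshold counts, full-reference segmentation quality
    metrics (RMSE, PSNR, SSIM, and FSIM with a log-Gabor phase-congruency
    map), and a synthetic generator of thermogram-like multimodal images
    for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
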
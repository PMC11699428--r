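Package: abmff
Title: Hybrid Agent-Based and Firefly-Clustering Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase grayscale image segmentation. Phase one is an
    agent-based model in which every pixel is an agent that nudges its
    intensity by a fixed step toward the sign consensus of its
    neighborhood, homogenizing regions and absorbing impulse noise.
    Phase two clusters the homogenized intensities with a firefly
    metaheuristic optimizing a regularized within/between-cluster
    objective, refined by K-means, and assigns every pixel to its
    nearest centroid. Includes a multilevel Otsu baseline,
    full-reference quality metrics (PSNR, global SSIM, FSIM with a
    log-Gabor phase-congruency bank), a generator of ground-truthed
    synthetic test images with Gaussian-region and impulse/additive
    noise models, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
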
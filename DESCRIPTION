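Package: vasquant
Title: Quantitative 3D Analysis of Embryonic Cerebral Vasculature
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-analysis toolkit for quantifying the three-dimensional
    cerebral vasculature of zebrafish embryos imaged by light sheet
    fluorescence microscopy. Provides tubular enhancement (Sato vesselness)
    and Otsu segmentation, slice-drift correction, landmark-based and
    automatic rigid inter-sample registration, population average maps,
    image similarity metrics (Dice, Jaccard, total overlap, mutual
    information, SSD, MSE, SSIM), an eight-parameter vascular morphometry
    stack (volume, surface, density, distance maps, 3D skeletonisation,
    network length, branch points, vessel radius, Sholl complexity),
    left-right symmetry analysis, synthetic vascular phantoms with exact
    ground truth, and group-level reporting with coefficient-of-variation,
    percent-difference and condition-clustering summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
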
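Package: gbmseg
Title: Unsupervised Multiparametric Segmentation of Glioblastoma from
    Multichannel MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully unsupervised segmentation of glioblastoma from
    co-registered multichannel MR volumes (T1, post-contrast T1, T2,
    FLAIR). Builds a 20-image first-order texture feature stack, reduces
    it with principal component analysis, classifies voxels with K-means,
    fuzzy K-means, Gaussian mixture models or a Gaussian hidden Markov
    random field fitted by hard expectation-maximization with iterated
    conditional modes, using a multi-start K-means++ initialization
    protocol. Pathological classes are isolated automatically with
    atlas tissue probability maps, morphological outlier removal and
    Jensen-Shannon-divergence class merging, and mapped to BRATS label
    codes. Includes a synthetic brain phantom generator, segmentation
    quality metrics (Dice, PPV, sensitivity, Cohen's kappa) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
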
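Package: ventbench
Title: Perturbation-Grounded Benchmarking of Saliency Methods for Brain-Age
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates gradient-based attribution (saliency) methods for 3D
    convolutional brain-age regression against a synthetic, perturbation-derived
    ground truth. Generates phantom T1-weighted-like volumes with FreeSurfer-style
    segmentations in which lateral-ventricle size grows with age, applies an
    age-proportional ventricular dilation to build paired non-dilated/dilated
    training cohorts, trains paired 3D convolutional regressors, computes seven
    attribution methods (gradient, input x gradient, masked gradient, guided
    backpropagation, GradCAM, guided GradCAM, integrated gradients, gradient
    SHAP), and scores the resulting saliency densities against the known
    perturbation support with Dice, normalized mutual information, normalized
    scanpath saliency, Pearson correlation, and histogram-intersection
    similarity, including percentage-difference tables against the
    masked-gradient baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
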
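Package: spnmtf
Type: Package
Title: Spatially Informed Semi-Nonnegative Matrix Trifactorization for Coclustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coclustering of molecular signals and spatial pixels in mass
    spectrometry imaging and related spatial omics experiments.  Approximates
    an n x p expression matrix by the product F mu G' of two cluster indicator
    matrices and a real-valued centroid matrix, while modelling spatial
    correlation among pixels through an exponential kernel: the loss is the
    squared Frobenius norm of the column-whitened residual, equivalently the
    kernel of a matrix-variate Gaussian likelihood with identity row covariance
    and covariance tau*K(S; phi) across columns.  Provides exact, approximate
    and stochastic label update steps, a closed-form update of the marginal
    variance, multi-restart fitting with kernel-scale grid search, a synthetic
    data generator with spatially contiguous column clusters, classification
    error rate metrics, and delimited-text input/output with a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, jsonlite, optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
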
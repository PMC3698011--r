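Package: qualpress
Title: Lossy Compression of FASTQ Quality Scores by Rate-Distortion
    Optimal Bit Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compresses the quality-score stream of fixed-length-read FASTQ
    files under a user-specified bit budget. Quality vectors are modelled as
    multivariate Gaussian, optionally pre-clustered with k-means,
    decorrelated through the eigendecomposition of their empirical
    covariance, assigned bits per transform coefficient by reverse
    water-filling, and quantized with Lloyd-Max codebooks for the unit
    Gaussian. Includes a binary container format with a bit-exact decoder,
    distortion (MSE) and storage accounting, and a synthetic FASTQ generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
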
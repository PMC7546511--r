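Package: twoStepSplice
Title: Two-Step Mixed-Model Analysis of Differential Transcript Expression and Splicing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects genes with differentially expressed and/or differentially
    spliced transcript isoforms from isoform-level RNA-seq abundance estimates
    (FPKM/TPM). Log-scale isoform abundances for each gene are modelled with a
    split-plot linear mixed effects model with a per-sample random effect and
    heterogeneous residual variances across isoforms (compound-symmetry and
    unstructured covariances are also supported). Inference is a two-step
    hierarchical procedure that controls the gene-level overall false discovery
    rate (OFDR): gene-level likelihood-ratio screening tests corrected by
    Benjamini-Hochberg, followed by per-isoform confirmatory Wald contrasts or
    t-tests with family-wise error control at the reduced level within each
    screened gene. A simulation engine estimates realized OFDR and power for
    the procedure and for a naive isoform-by-isoform comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
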
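Package: enhancerscan
Title: Two-Stage Enhancer Prediction and Boundary Localization from
    Epigenetic Signals and DNA Sequence
Version: 0.1.0
Authors@R: person("enhancerscan", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Predicts whether 4000 bp genomic regions contain enhancers from
    flexible combinations of binned epigenetic signals (DNase-seq and histone
    ChIP-seq) using a blending ensemble whose meta-classifier is a
    Kolmogorov-Arnold network (KAN) implemented from scratch, then localizes
    enhancer boundaries within positive regions by scoring 200 bp sliding
    windows with a stacking ensemble and merging high-probability windows
    under a dynamic threshold. Includes a synthetic-data generator emulating
    enriched signal bumps, planted enhancer sequences and Gaussian noise so
    the full pipeline is testable without external downloads, plus
    evaluation metrics (accuracy, sensitivity, specificity, MCC, AUROC,
    AUPRC) and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    glmnet,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
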
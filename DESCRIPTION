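Package: txentropy
Title: Information-Theoretic Quantifiers for Transcriptome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes information-theoretic quantifiers of probe-by-sample
    expression matrices: normalized Shannon entropy of each sample's
    expression probability profile, Jensen-Shannon divergence to
    configurable reference profiles (uniform, group averages), and the
    MPR- and modified (M-) statistical complexities used to place samples
    on complexity-entropy planes for tumour progression staging. Includes
    the dataset-conditioning steps these analyses require (missing-value
    imputation, removal of probes with missing cells, spike-probe
    filtering, sample exclusion), probe ranking by Pearson/Spearman
    correlation of expression with any sample-level quantifier together
    with sign-reversal and difference rankings for biomarker discovery,
    a seeded synthetic expression-matrix generator with planted ground
    truth for recovery testing, and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
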
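Package: pandosage
Title: Gene-Family Copy Number, Pan-Genome and Dosage-Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying copy-number variation and dosage balance in
    plant gene families, built around the melatonin-pathway O-methyltransferases
    (ASMT/COMT). Covers homology-hit filtering and subfamily labelling,
    per-species copy-number tabulation, greedy protein clustering into
    orthologous gene groups with Core/Shell/SoftCore/Cloud occupancy classes,
    pan-genome openness curves with power-law fits, Nei-Gojobori Ka/Ks
    estimation with Jukes-Cantor correction, Gaussian-mixture decomposition of
    Ks distributions with BIC model selection and divergence-time conversion,
    collinearity block chaining with duplication-type classification, and the
    dosage-balance statistics (subfamily regressions, k-means high/low splits,
    receptor correlation, ploidy contrasts, expression comparisons). Includes
    synthetic-data generators with recorded ground truth so every stage is
    testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
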
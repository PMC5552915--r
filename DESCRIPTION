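Package: phoscreen
Title: Profile-HMM Screening of Phosphorus-Scavenging Genes in Soil
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for quantifying phosphorus-scavenging
    gene families (alkaline phosphatases PhoX, PhoD, PhoA; nonspecific
    acid phosphatases; related enzymes) in predicted-CDS protein sets
    from soil metagenomes.  Builds position-specific profile hidden
    Markov models from curated family alignments, scores CDS fragments
    by forward and Viterbi log-odds in a local alignment mode,
    normalizes hit counts to single-copy housekeeping genes (RecA,
    RpoB, AtpB, GyrB, SucD) to obtain per-site genome equivalents and
    per-genome gene frequencies, compares low-pH versus high-pH site
    groups with unpaired t-tests, assigns hits to taxa by best-hit
    protein alignment against a lineage-labeled reference database with
    Krona-compatible export, and simulates metagenome communities with
    planted, known gene-carriage fractions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
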
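Package: edscape
Title: Mapping the Cis-Regulatory Landscape of A-to-I RNA Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cis-regulation of adenosine-to-inosine (A-to-I)
    RNA editing in panels of inbred lines. Quantifies per-site editing levels
    from targeted amplicon read counts with coverage and replicate-concordance
    filters, maps editing quantitative trait loci (edQTLs) by
    permutation-calibrated linear-model association with Storey q-value FDR
    control, predicts editing complementary sequences (ECSs) by extracting
    long, low-bulge stems from folded RNA secondary structure (proximal
    windows and conserved distal intronic candidates), and interprets edQTLs
    structurally through allelic duplex free-energy comparison and discovery
    of secondary dsRNA stems. Includes a fully seeded synthetic-data generator
    that plants edQTL effects and dsRNA duplexes so every stage can be tested
    against ground truth, and a deterministic built-in minimum-free-energy
    folding engine with a pluggable structure interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
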
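Package: droshascan
Title: Discovery and Characterization of Drosha Cleavage Sites from
    Degradome and Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects endonucleolytic cleavage sites of the nuclear RNase III
    enzyme Drosha from Degradome-seq (PARE) 5'-start pile-ups, reconstructs
    the cleaved stem-loops by pairing Degradome anchors with small-RNA-seq
    terminus stacks under the RNase III 3' 2-nt overhang rule, and
    characterizes the thermodynamic, structural and sequence-motif features
    that distinguish miRNA from non-miRNA substrates. Includes a fully
    verifiable built-in RNA secondary-structure engine (minimum free energy,
    partition function, positional entropy, ensemble diversity), a
    resampled-negative consensus classifier for pile-up detection,
    TMM-normalized negative-binomial differential testing of cleavage-site
    depletion, and a synthetic-data generator that plants ground-truth
    hairpins for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    glmnet,
    edgeR,
    readr,
    stringr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    jsonlite,
    withr
Config/testthat/edition: 3
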
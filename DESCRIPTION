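Package: ncldvscope
Title: Marker-Gene Quantification and Host Association Screening for Giant
    Viruses in Size-Fractionated Marine Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for profiling nucleo-cytoplasmic
    large DNA viruses (NCLDVs) in size-fractionated marine metagenomes:
    removal of 454-style artificial duplicate reads, six-frame peptide
    extraction, dual-BLAST last-common-ancestor (2bLCA) taxonomic annotation
    with an adaptive per-protein E-value threshold, single-copy marker-gene
    density estimation rescaled to absolute genome concentrations via
    prokaryote cell counts, compositionality-aware taxon co-occurrence
    networks (Spearman and Kullback-Leibler scores, permutation-
    renormalization null, Brown-combined p-values), and a taxonomically
    masked reciprocal-best-hit screen for virus-cell horizontal gene
    transfer. A synthetic-data module generates every input with known
    ground truth so all stages can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
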
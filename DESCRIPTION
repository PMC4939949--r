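Package: profasm
Title: Profile HMM Guided Assembly and Homology Search for Short Peptide Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Searches profile hidden Markov models of protein families against
    databases of short peptide reads (such as fragmentary gene-caller
    translations of metagenomic or metatranscriptomic sequencing reads) by
    simultaneous alignment and assembly: reduced-alphabet k-gram seeding,
    banded Viterbi extension of contigs along an exact suffix-prefix overlap
    graph, full-model verification with extreme-value significance
    statistics, and recruitment of reads onto trusted contigs. Reports
    per-family read counts and RPKM abundances, recall/precision/F-measure
    against ground truth, and contig statistics (N50, normalized N50,
    read- and contig-level precision). Includes a synthetic-data module that
    emits homologs from a profile HMM, embeds them among decoy proteins and
    fragments them into error-bearing peptide reads with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
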
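Package: codonscope
Title: Codon Usage Bias Analysis for Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for analysing synonymous codon usage
    bias in sets of coding DNA sequences, modelled on the classical codonW
    workflow applied to the silkworm (Bombyx mori) transcriptome. Provides
    quality filtering of CDS FASTA input; per-gene indices (GC partitions,
    silent-site base composition, relative synonymous codon usage, Wright's
    effective number of codons, codon adaptation index, GRAVY, aromaticity);
    correspondence analysis of RSCU and amino-acid usage; mutation-versus-
    selection diagnostics (ENc-GC3s plot, ENc deviation distribution,
    neutrality regression of GC12 on GC3, Spearman correlation matrices);
    chi-squared identification of translationally optimal codons from
    ordination-extreme gene pools; comparison against Kazusa-format codon
    usage tables of other organisms; and a seeded simulator of coding
    sequences with controllable codon-preference structure for validation.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
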
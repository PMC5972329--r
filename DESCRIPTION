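Package: tcrshm
Title: Somatic Hypermutation Profiling of T Cell Receptor cDNA Clone Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Characterizes somatic hypermutation (SHM) in T cell receptor
    alpha cDNA clone repertoires. Infers germline references and allelic
    positions from clone pools, genotypes constant-region allotypes, flags
    PCR-jumping chimeras, clusters V families, and assigns J segments;
    calls and classifies substitution and indel events (transition or
    transversion, replacement, synonymous, nonsense, frameshift); computes
    mono-, di- and trinucleotide mutability indices (observed over
    composition-expected mutation counts) with per-k-mer chi-square
    significance; scans AID hotspot (RGYW/WRCY) and polymerase-eta (WA/TW)
    motifs and the fraction of mutations at motif-mutable positions;
    discovers candidate J gene segments in genomic scaffolds via core-motif,
    recombination-signal-sequence and splice-donor rules; and generates
    truth-tagged synthetic repertoires so every stage has a
    parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    tidyr,
    withr
Config/testthat/edition: 3
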
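Package: pairem
Title: Simulation and Analysis of Natively Paired Antibody Heavy/Light
    Chain Repertoires from Emulsion Overlap-Extension Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paired B-cell receptor repertoire sequencing in which
    heavy and light chain mRNAs from single rough-ER microsomes are fused into
    one amplicon inside emulsion droplets. Provides a generative simulator of
    the whole assay (skewed clonal repertoires, Poisson droplet encapsulation,
    nested-PCR chimera formation, 2x250 paired-end MiSeq-like reads with
    ground-truth tags) and the matching analysis pipeline: quality and
    amplicon-structure filtering, V/J assignment and CDR3 extraction against a
    toy germline reference, clonotype clustering with PCR-error correction,
    VH-VK pairing matrices, clonal-share and light-chain promiscuity
    statistics, spike-in pairing accuracy, longitudinal clonotype tracking,
    and defined-amplicon chimera quantification.
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
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
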
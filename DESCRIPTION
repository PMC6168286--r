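Package: spikechip
Title: Spike-In Calibrated ChIP-Seq and Strand-Specific RNA-Seq
    Quantification for Ageing Yeast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies histone-mark redistribution in genomes whose copy
    number changes with age, as in replicatively ageing budding yeast where
    the rDNA array amplifies massively through extrachromosomal rDNA
    circles. Implements reference-chromatin (spike-in) normalization of
    ChIP-seq via per-sample factors computed from dual-genome read counts,
    dual-genome read disambiguation, copy-number-corrected coverage in
    tiled 1 kb windows, rDNA/euchromatin compartment accounting, promoter
    and TSS-anchored metagene quantification over an unambiguous-promoter
    gene set, strand-specific RNA-seq normalization on mRNA-derived ORF
    reads, antisense (pervasive) transcription quantification, and an
    age-versus-histone-depletion expression filter. A synthetic-data
    generator with a full latent-truth record emulates the paired
    two-genome experimental design so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
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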
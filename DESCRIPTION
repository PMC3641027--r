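Package: lepitran
Title: Tiered Homology Annotation and Expression Analysis for De Novo
    Insect Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for characterizing de novo insect
    transcriptome assemblies from short-read RNA-Seq, modelled on gypsy
    moth (Lymantria dispar) larval midgut studies of the response to
    Bacillus thuringiensis infection.  Provides read quality control
    (Phred conversion, terminal clipping, quality-fraction filtering and
    low-quality base masking), alignment-based ribosomal RNA depletion,
    tiered homology classification of assembled transcripts from BLASTX
    tabular reports (gold/silver/bronze), CDS trimming and translation,
    functional annotation rollups (Pfam top hits, pfam2go, GO-Slim
    penultimate ancestors, kegg2go), digital gene expression with
    total-read normalization and fold-change ranking, and qRT-PCR
    relative expression via 2^-deltaCt.  A synthetic-data generator
    plants tier destinies, abundance fold changes, rRNA contamination
    and Ct tables with known ground truth so every stage is testable
    without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
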
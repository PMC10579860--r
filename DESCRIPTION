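Package: genecurate
Title: Curation Toolkit for Manual Protein-Coding Gene Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates proposed protein-coding gene models against genome
    scaffolds using a biological-constraint checklist (start/stop codons,
    canonical splice sites, splice-phase compatibility, open reading frame),
    refines approximate coding-exon boundaries, finds phase-constrained small
    exons, applies consensus-error corrections from VCF edit files with
    coordinate liftover, merges per-isoform GFF/FNA/FAA annotation outputs,
    assigns orthologs by reciprocal best hits and local synteny, and reconciles
    independently built gene models into a classified discrepancy report.
    Includes a deterministic synthetic-locus generator so the whole toolkit is
    testable without external data.
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
    rlang,
    tibble,
    vcfR
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
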
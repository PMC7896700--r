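Package: beclone
Title: Subclone Deconvolution and Phylogenetic Statistics for
    Multi-Biopsy Barrett's Esophagus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated within-patient subclone deconvolution for
    multi-biopsy whole-genome sequencing of Barrett's Esophagus.
    Partitions somatic SNVs by the subset of biopsies in which they are
    detected, locates variant-allele-frequency peaks by kernel smoothing
    and Gaussian-mixture weighting, assembles each patient's clonal
    lineages into a phylogenetic forest with per-tip cell fractions,
    assigns SNVs to branches to obtain branch lengths, and places
    functional candidate-locus mutations with inferred zygosity.
    Includes branch-length-weighted permutation and resampling tests for
    spatial and temporal clustering (Fitch and ordered-trait parsimony),
    subclonality, clonal expansion, dispersion, and mutation ordering,
    with Benjamini-Hochberg correction, plus a synthetic-cohort
    simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
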
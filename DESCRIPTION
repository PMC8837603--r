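Package: npstminer
Title: Mining PABA-Specific NRPS Adenylation Domains from Metagenomic
    Amplicon Libraries
Version: 0.1.0
Authors@R:
    person("npstminer", "developers", email = "npstminer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a culture-independent pipeline for
    discovering non-ribosomal peptide synthetase (NRPS) gene clusters that
    polymerize p-aminobenzoic acid (PABA) in soil metagenomes. Provides
    degenerate-primer in-silico PCR against the conserved A3/A7 adenylation
    domain regions, de-barcoding and greedy 95% identity clustering of
    amplicon reads into natural product sequence tags (NPSTs), a two-step
    PABA screen (Smith-Waterman/Karlin-Altschul E-value filter against
    characterized PABA A-domains followed by a degenerate nucleotide
    signature), neighbor-joining phylogenetics with metagenome-only clade
    calling, extraction of the 10-residue substrate-binding-pocket
    (Stachelhaus) code with nearest-code substrate prediction, and a rule
    engine that converts an annotated NRPS architecture into a monomer-level
    structure prediction (lipo-initiation, trans-complemented A-domains,
    thiazoline/thiazole heterocycles, PABA tailoring). A seeded synthetic
    metagenome generator makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
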
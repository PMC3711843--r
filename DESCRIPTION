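Package: transmark
Title: Transcriptome SNP Mining, Paralog Discrimination and KASP Target Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for developing single-nucleotide polymorphism (SNP) and
    microsatellite (SSR) markers from de novo assembled transcriptome contigs
    of a paleopolyploid crop against a reference coding-sequence set. Contigs
    are grouped to reference gene models by seeded local alignment, SSRs are
    detected with MISA-style perfect-repeat thresholds and compared between
    lines under a strict flank-identity rule, inter-line SNPs are called from
    homolog alignments and filtered on read depth and quality, allelic SNPs
    are separated from paralog-specific variations (PSVs) in duplicated gene
    families, and surviving SNPs are turned into KASP-style 101 bp assay
    target sequences through a three-criteria filter cascade (conserved 50 bp
    flanks, no exon-intron junction in the window, read depth of at least 7).
    A synthetic-data generator with machine-readable planted ground truth and
    two-point recombinant-inbred-line (RIL) linkage utilities (segregation
    distortion, recombination fractions, LOD grouping, Kosambi distances)
    support end-to-end validation without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
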
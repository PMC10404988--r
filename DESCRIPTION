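Package: v9var
Title: Intragenomic Variability of the 18S rRNA V9 Barcode and Its Effect on
    OTU-Based Diversity Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring intragenomic variability of the V9
    hypervariable region of the 18S rRNA gene and for quantifying how the
    choice of OTU definition (single-linkage d=1 "swarm" clustering,
    error-model based denoising, or greedy 97% centroid clustering) inflates
    or deflates eukaryotic diversity estimates. Includes a synthetic-data
    generator for multi-copy rRNA loci with configurable intragenomic
    variants, quality-dependent sequencing errors, contamination and
    chimeras; V9 reference extraction by degenerate-primer location; read
    quality filtering and pair merging; similarity-based V9 extraction and
    dereplication into barcodes; a divisive amplicon denoiser with
    self-consistent error-rate learning and consensus bimera removal;
    identity-based contamination classification; and per-genome and
    cross-protocol diversity metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
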
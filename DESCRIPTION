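Package: orthosnp
Title: Lineage-Specific Selection Screens on Four-Taxon Orthogroup Codon Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transcriptome-wide screen for lineage-specific non-synonymous
    substitutions under positive selection in single-copy orthogroups of four
    taxa. Implements filtering of codon alignments (pairwise identity and
    length thresholds), variant calling from alignments with outgroup
    polarization and codon-aware effect classification, dN/dS estimation by
    Nei-Gojobori (1986) counting with Jukes-Cantor correction and by maximum
    likelihood under the Goldman-Yang (1994) M0 codon model on a fixed
    quartet topology, candidate-gene assembly, and comparative annotation
    statistics (exact binomial 50:50 acceptance regions, Fisher and
    chi-squared contingency tests, Benjamini-Hochberg enrichment scans, and
    two-proportion comparisons). A synthetic-data generator evolves codon
    alignments on the quartet tree with per-branch selection regimes and
    plants ground-truth candidates, contaminants, and annotation asymmetries
    so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
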
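Package: plastidkit
Title: Heteroplasmy, Phylogenomics, Divergence Dating and Structural
    Variation from Deep Plastid Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of deeply resequenced plastid
    genomes. Builds masked multi-sample haploid variant matrices from
    per-position allele-count pileups, calls single heteroplasmic
    positions from minor-allele read support and tests putative paternal
    parents of hybrids by heteroplasmy compatibility, infers SNV-based
    phylogenies with bootstrap support, evaluates GTR likelihoods with
    and without a molecular clock and performs the clocklikeness
    likelihood-ratio test, dates nodes by penalized likelihood with
    autocorrelated rates and cross-validated smoothing, scans genes for
    clade-specific shifts in dN/dS with a counting-based branch-omega
    model, and detects large deletions with breakpoint microhomology
    annotation. Includes a seeded simulator of chloroplast-like genomes,
    timed-tree evolution with hybridization leakage, and deep pileups,
    so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
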
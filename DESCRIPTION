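Package: sweepscan
Title: Selective-Sweep Scans from Windowed Tajima's D with
    Beta-Approximation Neutral Ranges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic analysis of multi-group domestication
    cohorts from diploid genotypes. Computes windowed diversity statistics
    (segregating sites, nucleotide diversity, Watterson's theta, Tajima's
    D), derives the per-sample-size neutral range of Tajima's D from its
    beta approximation, calls candidate selected windows by an
    intensity-exceedance rule, combines subgroup calls with set logic to
    separate selection regimes acting on different cultivated groups, and
    corroborates calls with reduction-of-diversity (ROD) and Hudson-type
    Fst. Also classifies SNPs by genomic context and coding effect against
    a reference annotation, profiles per-accession heterozygosity under
    selfing, measures linkage-disequilibrium decay, and performs
    0/1/2-dosage principal component analysis. Ships a deterministic
    synthetic-cohort generator (reference FASTA, GFF3 gene models, VCF,
    sample groups, truth BED) so the whole pipeline is testable without
    resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
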
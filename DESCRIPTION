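Package: vigorkit
Title: Selection Scans, Binding Kinetics and Seed-Vigor Phenotype Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the quantitative stages of a maize
    seed-vigor locus study: windowed Weir-Cockerham FST and nucleotide
    diversity selection scans with permutation and coalescent
    domestication-bottleneck null thresholds; dissociation-constant fitting
    of protein-poly(A) mRNA binding series under ligand depletion with
    replicate resampling, Scheffe and Monte-Carlo Dunnett statistics;
    paired RNA-seq/RNC-seq translation-efficiency testing with a
    five-category gene classification; McrBC-qPCR and locus-specific
    bisulfite CG/CHG/CHH methylation quantification; germination
    time-course and amplicon-haplotype statistics; and neighbor-joining
    protein phylogenies with Poisson correction and bootstrap supports.
    Synthetic-data generators emulate every input so the full pipeline
    runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    seqinr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mvtnorm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
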
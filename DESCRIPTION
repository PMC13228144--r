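Package: selfpop
Title: Population Genomics of Predominantly Selfing Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the population-genomic analysis of predominantly but
    not obligately selfing organisms from unlinked biallelic SNP genotypes.
    Implements multilocus selfing-rate estimation from identity
    disequilibrium (the g2 statistic, with permutation tests and locus
    bootstrap), forward simulation of partially selfing lineages under a
    geometric selfing-ancestry model, maximum-likelihood admixture-model
    ancestry inference by EM, hybrid-class simulation with an envelope-based
    recency-of-admixture classifier, KING-robust kinship screening, folded
    site-frequency spectra with hypergeometric projection, and
    divergence-time conversion. Includes genotype I/O for VCF, two-row
    STRUCTURE and plain 0/1/2 matrix formats, and a seeded synthetic-data
    generator emulating a multi-lineage invasion study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
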
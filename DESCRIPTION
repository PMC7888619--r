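Package: triotwas
Title: Trio-Based Transcriptome-Wide Association Analysis with
    Pseudo-Sibling Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Family-based transcriptome-wide association testing for
    proband-parent trios.  From phased parental haplotypes the package
    constructs the four Mendelian pseudo-offspring genotype configurations
    per family and cis-window, imputes genetically regulated expression
    with linear SNP-weight models, matches each proband with three
    pseudo-sibling controls (or the one-sibling and parent-control
    alternatives) and estimates transmission disequilibrium of imputed
    expression by conditional logistic regression.  Companion statistics
    include trio GWAS on single-variant allele counts, inverse-variance
    and sample-size-weighted meta-analysis, the polygenic transmission
    disequilibrium test, hypergeometric gene-set and Poisson de novo
    mutation enrichment, coexpression and spatiotemporal permutation
    tests, and a synthetic-trio simulator used for type-I-error, noise
    robustness and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
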
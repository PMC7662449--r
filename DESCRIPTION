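Package: pathGBC
Title: Genomic Breed Composition for Composite Animals by Path Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates genomic breed composition (GBC) of crossbred and
    composite animals from SNP genotypes and reference-breed allele
    frequencies. Implements three estimators: adjusted linear regression of
    coded genotypes on breed allele frequencies, a supervised admixture
    model maximising a binomial likelihood under Hardy-Weinberg equilibrium,
    and a causal path-analysis decomposition that partitions the
    determination of a composite genome into direct (D-GBC) and combined
    (C-GBC, including correlational indirect effects) contributions of each
    ancestral breed via Wright's path coefficients. Also provides a path
    diagram engine implementing Wright's compound-path rules for multi
    generation pedigrees, reference-panel purity filtering via a genotype
    likelihood score, uniform SNP panel selection, and a Balding-Nichols
    simulator of reference breeds and crossbred genotypes so every
    estimator can be exercised without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
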
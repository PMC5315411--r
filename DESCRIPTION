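Package: trilocus
Title: Multi-Locus Genetic Risk Analysis for Canine Dermatomyositis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical machinery for dissecting the three-locus genetic
    architecture of canine dermatomyositis (DMS): dog leukocyte antigen (DLA)
    class II haplotype case-control association with exact tests and Woolf
    confidence intervals, penetrance estimation and risk classification over
    the 27 PAN2 x MAP3K7CL x DLA-DRB1 genotype combinations, a hierarchical
    Bayesian logistic model of additive, dominance and epistatic effects on
    disease probability, a Bayesian Weibull model of age at onset by
    risk-allele count, dominant-model Fisher GWAS with Hardy-Weinberg and
    call-rate quality control and LD-based candidate-interval demarcation,
    a pooled-heterozygosity (ZHp) selective-sweep scan with creeping windows,
    and segregation-based filtering of whole-genome sequence variants.
    Includes synthetic-cohort generators that emulate the breed-specific
    allele frequencies, penetrance architecture and linkage structure the
    analyses assume, so every stage can be exercised without raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
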
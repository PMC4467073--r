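Package: igcscan
Title: Detecting Interlocus Gene Conversion Signals from Shared
    Polymorphisms in Segmental Duplications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate signals of interlocus gene conversion
    (IGC) as "parallelisms": pairs of single nucleotide polymorphisms at
    one-to-one aligned positions of paralogous segmental duplications
    that segregate identical alleles.  Provides global pairwise
    alignment of paralog pairs with alignment-quality masking (windowed
    identity, local Hamming distance, indel and edge exclusion),
    strand-aware shared-allele classification of aligned SNP pairs,
    read-uniqueness and CpG filters, grouping of higher-order
    parallelisms, and an estimator of the fraction of SNPs attributable
    to IGC.  Mutation-only null models include the one-third rule for
    parallel mutation, coalescent simulations conditioned on segregating
    sites under recent exponential growth, permutation tests for
    genomic-context enrichment and population sharing, a window
    clustering test, and clone-pool validation rules.  A fully labelled
    synthetic-data generator produces paralog pairs, population SNP
    cohorts, injected IGC tracts with ground truth, read-mapping
    metadata and clone pools for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
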
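Package: heterogen
Title: Additive and Dominance Genomic Dissection of Heterosis in Crossbred Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioning the genetic variance of quantitative traits
    in crossbred (F1) populations into additive and dominance components and for
    mapping the loci behind each component. Implements body-weight endpoint
    adjustment of age and backfat records to 100 kg, mid-parent heterosis,
    VanRaden additive and heterozygosity-coded dominance genomic relationship
    matrices, a two-kernel mixed model fitted by average-information REML or by
    a Gibbs sampler, partial genetic values (additive and dominance BLUPs used
    as derived phenotypes), single-locus and stepwise multi-locus mixed-model
    association scans with Bonferroni thresholds and ensemble combination,
    nearest-gene annotation, and a seeded simulator of F1 crosses and QTN
    architectures for power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
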
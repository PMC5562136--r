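Package: pisasterDE
Title: Genotype-Contrast RNA-Seq Differential Expression with Permutation
    Robustness Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Negative-binomial differential expression analysis for small
    two-class RNA-seq designs, built around the constitutive-expression
    contrast between EF1A insertion heterozygotes and wild-type homozygotes
    in the ochre sea star Pisaster ochraceus. Provides count aggregation
    across transcript, gene and homology levels, CPM filtering, TMM
    normalization, quantile-adjusted conditional maximum likelihood
    dispersion estimation with empirical Bayes tagwise shrinkage, the exact
    negative-binomial two-group test, a paired negative-binomial
    likelihood-ratio test, sorted and unsorted label-permutation robustness
    tests of the class partition, outlier-library influence diagnostics,
    righting-response behavioral comparisons, and a synthetic-data generator
    that emulates the paired two-temperature study design with planted
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
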
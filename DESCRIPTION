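Package: refbias
Title: Quantifying and Mitigating Reference Bias in Ancient DNA Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for measuring, diagnosing and mitigating reference bias
    in short-fragment (ancient DNA) sequencing data. Provides allelic-balance
    metrics at known heterozygous transversion SNPs under mapping- and
    base-quality filters, a virtual opposite-allele read-set diagnostic with
    exact allelic-balance binning, two post-mapping remapping filters
    (allele-flipped reads and a third-allele modified reference) and their
    combination, pseudo-haploid genotype sampling, D and f4 statistics with
    the weighted block jackknife, and an f4-ratio ancestry estimator. A
    deterministic internal short-read mapper emulating length-scaled edit
    budgets, a 35-mer mappability mask, and synthetic-data generators
    (degraded fragments with terminal deamination, contamination and
    controllable repeats) make every analysis exercisable end-to-end without
    external aligners or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
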
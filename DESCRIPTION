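Package: hapint
Title: Haplotype Odds-Ratio Interaction Tests for Case-Control SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene-gene interaction (epistasis) between pairs of
    biallelic loci from unphased case-control genotype data using a
    pseudohaplotype odds-ratio interaction statistic. Two-locus haplotype
    frequencies are estimated per group by an expectation-maximization
    algorithm; the interaction measure is the between-group difference of log
    haplotype-frequency cross-ratios, tested against a chi-squared
    distribution with one degree of freedom via a delta-method variance.
    Includes case-only and comparator tests (allele-based "fast-epistasis"
    and logistic-regression interaction), a two-locus penetrance-model
    simulator for type I error and power studies, and a pairwise genome-scan
    pipeline with quality-control filters, PLINK text and binary input,
    false-discovery-rate control, quantile-quantile diagnostics and
    two-dataset replication logic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
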
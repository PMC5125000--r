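Package: mdewas
Title: Methylation-Disequilibrium Blocks and Methylecomtype Association Scans
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control epigenome-wide association analysis on combinations of
    binarized DNA-methylation levels. Beta-value matrices (e.g. Illumina 450K)
    are thresholded into high/low methylation levels; non-random association
    between neighbouring CpG loci ("methylation disequilibrium") is quantified
    with D-prime- and r-squared-style coefficients; chromosomes are partitioned
    into MD blocks with a Gabriel-type confidence-interval rule applied through
    an elastic sliding window; and per-block methylation-level combination
    types ("methylecomtypes") are tested for case/control association with
    chi-square statistics, odds ratios and confidence intervals. Includes a
    per-locus Welch t test on raw beta values, a synthetic-data generator with
    planted blocks and effects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
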
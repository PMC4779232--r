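Package: curvegroup
Title: Curve Group Analysis of Longitudinal Case-Control Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Permutation-based detection of development over time in gene
    expression from matched case-control pairs, and comparison of that
    development between strata. Genes are classified into curve groups by the
    ordering of their per-time-period mean log2 case-minus-control differences;
    within-stratum time trends are tested through curve-group membership counts,
    and strata are compared through curve-group-variable averages and a weighted
    sum of absolute two-sample t-statistics. Includes generic preprocessing for
    paired expression data (log2 differences, quantile normalization, presence
    filtering, probe collapse), a synthetic-data generator emulating the paired
    design with inter-gene correlation, a type-I error / power estimation
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
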
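Package: duometh
Title: Parallel Bisulfite/Oxidative-Bisulfite Methylome Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "duometh", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the joint analysis of 5-methylcytosine (5mC) and
    5-hydroxymethylcytosine (5hmC) from paired whole-genome bisulfite (WGBS)
    and oxidative bisulfite (oxWGBS) sequencing of tumor and matched normal
    tissue. Includes a self-contained synthetic study generator (annotation,
    true methylome with implanted differential regions, binomial read
    sampling with realistic conversion chemistry, spike-in controls,
    expression), spike-in conversion-rate QC, per-CpG beta calling with
    coverage filtering, closed-form constrained maximum-likelihood
    estimation of (5mC, 5hmC) from the paired arms, differential
    (hydroxy)methylated region calling by recursive binary segmentation
    with exact rank tests, genomic-feature annotation, 30-bin metaprofiles
    and observed/expected enrichment, and integration of promoter
    modification patterns with gene expression (unidirectional versus
    bidirectional promoter classification, stratified fold changes, and
    signature scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
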
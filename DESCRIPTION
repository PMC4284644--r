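Package: twindmr
Title: Twin-Based Epigenome-Wide Association Analysis for Binned
    MeDIP-seq Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Differentially methylated region (DMR) discovery from binned
    MeDIP-seq methylation profiles in a monozygotic-twin case-control
    design.  Provides genome tiling and per-bin RPM quantification, a
    family random-intercept linear mixed model fitted by profiled REML
    for DMR scans, a within-pair paired test for genetically independent
    DMRs in disease-discordant twins, replication in unrelated samples,
    permutation and resampling enrichment tests against gene annotations
    and GWAS loci, cis/trans methylation-QTL scans with a causal
    inference (mediation) test, and run-day-normalized metabolite
    integration.  A seeded synthetic-data generator with recorded
    planted truth makes the whole pipeline testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    S4Vectors,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
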
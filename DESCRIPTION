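Package: poolsweep
Title: Selective-Sweep Scanning, Drift Nulls and Multi-Locus Association for
    Pooled Sequencing of Divergent Selection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing evolve-and-resequence experiments from pooled
    whole-genome sequencing. Implements the PoPoolation2 sync exchange format,
    site-level coverage filters, the Karlsson et al. ratio-of-sums F_ST
    estimator over sliding windows, percentile-cutoff clustering of windows
    into candidate selective-sweep regions, a forward Wright-Fisher simulator
    providing a neutral-drift null for region differentiation under a
    two-epoch breeding scheme, a synthetic-data generator emulating 39
    generations of bidirectional truncation selection on a polygenic trait
    with relaxed sublines and an F2 intercross, multi-locus
    backward-elimination association of highly differentiated markers under a
    two-tier false discovery rate criterion, and haplotype-frequency inference
    within sweep regions from pooled allele frequencies by reference-haplotype
    polarization.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
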
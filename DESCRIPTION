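Package: apavar
Title: Cell-to-Cell Variability in Alternative Polyadenylation Isoform
    Choice from Single-Cell 3' Tag Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying alternative polyadenylation (APA) isoform
    usage in single cells from 3' tag sequencing with unique molecular
    identifiers (UMIs), and for dissecting the observed cell-to-cell variance
    in isoform ratios into technical noise, random partitioning of molecules
    to isoforms, and true variability in isoform preference. Includes a read
    tag processing pipeline (UMI collapsing, polyadenylation site discovery
    and merging, gene assignment, internal-priming filters), spike-in based
    estimation of per-cell molecular capture efficiencies, a hierarchical
    Bayesian model of isoform preference fitted by MCMC with DIC model
    comparison, a one-factor extension that clusters cells by correlated
    shifts in isoform preference independent of expression level, and
    frequentist partition-null resampling tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rjags,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    readr,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
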
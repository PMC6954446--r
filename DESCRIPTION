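Package: vparcl
Title: Crosslink Site Calling and RNA Structure Integration for In-Virion
    Mutational Profiling
Version: 0.1.0
Authors@R:
    person("vparcl", "maintainers", email = "vparcl@example.org",
           role = c("aut", "cre"))
Description: Calls RNA-capsid crosslink sites (vPAR-CL) and single-stranded
    RNA signals (DMS-MaPseq) from per-position mutational profiles in
    sequencing data of purified virus particles. Covers read preprocessing,
    alignment pileup into base-count tables, fold-change signal maps with
    coverage masking and percentile background filtering, replicate consensus
    and significance calling, export of unpaired folding constraints and
    parsing of secondary-structure files, site-level structural context,
    double-strand enrichment and clustering statistics with analytic and
    Monte-Carlo nulls, plus a ground-truth read simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
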
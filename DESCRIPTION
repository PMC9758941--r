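Package: blastpart
Title: Performance-Model-Driven Data Partitioning for BLAST Jobs on HPC Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans optimal database and query fragmentation for BLAST-style
    two-input sequence-search jobs on high-performance computing clusters.
    Runtime surfaces are fitted as bivariate quadratics over database and query
    size from profiling measurements, turned into per-node-type performance
    models, and minimized over candidate (m, n) fragmentations by static
    load-balancing solvers for homogeneous and heterogeneous node inventories.
    The chosen plan is materialized as split FASTA fragments and executable job
    manifests that carry the effective database sequence count needed for
    correct E-values under database segmentation. Parsers for Unix time, gprof
    flat profiles, and stopwatch logs feed measurement tables; a synthetic
    benchmark module generates measurement grids, FASTA files, and profiler
    fixtures for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
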
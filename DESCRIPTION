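Package: chromgm
Title: Group Graphical Models of the Chromatin Network from Binned ChIP-seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates conditional-dependence ("chromatin") networks among many
    ChIP-seq data sets from raw binned read counts. Reads are binned into
    fixed-width genomic windows, a sample correlation matrix is inverted to
    obtain conditional dependencies, and collinear (redundant) data sets are
    handled with a group graphical model whose group-edge weights are sums of
    inverse-correlation entries between group members. Also provides per-bin
    edge-influence scoring via rank-one leave-one-out updates of the inverse
    correlation matrix, a count-valued ChIP-seq simulator with known
    dependence structure, enrichment-based evaluation of ranked edges against
    known protein-protein interactions with a factor-level bootstrap, and a
    deterministic resistance-distance 2D embedding of the network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
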
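Package: nucleoscape
Title: Nucleosome Landscape and Accessibility at CpG-Island Promoters from ATAC Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chromatin accessibility and nucleosome landscape
    features (occupancy, inter-dyad spacing, positional fuzziness) at
    CpG-island promoters from ATAC-style sequenced-fragment coordinates.
    Promoters are classified into Polycomb-bound and Polycomb-free sets by
    ChIP peak overlap, fragments are size-classified into nucleosome-free
    and mononucleosomal pools, and a kernel-density occupancy model calls
    nucleosome dyads whose spacing and fuzziness are summarised per
    promoter. Condition deltas and rank-based group statistics support
    perturbation analyses (for example loss of a Polycomb repressive
    complex). A seeded synthetic-fragment generator with recorded ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
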
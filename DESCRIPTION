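Package: isoforge
Title: Multi-Evidence Transcript Isoform Assembly and Transcriptome Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs full-length transcript isoforms by validating,
    correcting and completing long-read exon chains against independent
    evidence: 5' cap-tag (CAGE-style) transcription start site clusters,
    3' polyadenylation-tag end site clusters, and short-read splice
    junction support. Loci are partitioned into linkage groups and
    indivisible segments; each long read becomes a binary segment path
    that is classified as full-length, completed, merged, rescued or
    partial, and integrated with short-read-only transfrags into a final
    annotation. Downstream statistics cover density-based tag clustering,
    entropy-based tissue specificity, promoter/terminator switch scores,
    weighted 3'UTR length and alternative-polyadenylation calls,
    microexons, intronic start/end coupling events, a branching-process
    null model for alternative-splicing hotspots, polycistron detection,
    and sequence scanners for ORFs, uORFs, G-quadruplexes and U-rich
    elements. A multi-modal synthetic-data generator emulates every input
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
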
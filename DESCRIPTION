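Package: operonatlas
Title: Unify Heterogeneous Bacterial Genome Annotations into a Transcript and Operon Atlas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Merges gene and structured-RNA annotations from prioritized,
    heterogeneous resources into a non-redundant gene set using
    Jaccard-index overlap criteria, unifies transcription start and
    termination sites of differing positional resolution, infers 5', 3'
    and internal untranslated regions from site-to-gene associations, and
    assembles transcripts and operons by path enumeration on a directed
    transcript graph. Includes a synthetic-fixture generator with known
    ground truth for end-to-end validation, transcription-evidence
    scoring against tiling-array style signal, and GFF3 import/export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    withr,
    igraph,
    ggplot2,
    generics,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
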
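Package: cpgtl
Title: Detection and Characterization of CpG Traffic Lights from
    Methylation and Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies single CpG dinucleotides whose methylation level
    across samples correlates with the expression of a nearby gene ("CpG
    traffic lights"), using Spearman rank correlation over CpG-gene pairs
    with Benjamini-Hochberg control of the false discovery rate.  Provides
    strand-resolved coverage filtering of whole-genome bisulfite calls,
    strand-aware CpG-gene pair construction, region-average comparison
    analyses, permutation nulls, construction of composition- and
    distance-matched background CpG sets, and an enrichment battery over
    genomic annotations, per-base score tracks, chromatin-state
    segmentations, gene sets and transcription-factor binding-site
    position profiles.  Includes a fully deterministic synthetic-data
    generator with planted signal and a ground-truth manifest so the whole
    pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
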
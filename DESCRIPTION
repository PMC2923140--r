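Package: peaktools
Title: Subpeak Calling and Gene Annotation of ChIP-Seq Enrichment Regions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing utilities for ChIP-seq and ChIP-chip peak
    calls. Subdivides multimodal regions of signal enrichment into
    discrete subpeaks by comparing adjacent local maxima of the read-depth
    profile against a valley-depth threshold, and annotates peak loci
    against gene models: nearest non-overlapping downstream gene on each
    strand, nearest transcription start site, classification of
    within-gene hits into exon, intron and UTR components, and
    inter-dataset overlap with a Monte-Carlo enrichment P-value. Interval
    queries are served by a nested containment list index. Includes
    parsers for BED, GTF and WIG (fixedStep, variableStep and bedGraph)
    with all coordinates normalized to a zero-based half-open convention,
    and a generator of synthetic genomes, annotations and signal tracks
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    GenomicRanges,
    S4Vectors,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
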
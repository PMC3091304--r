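Package: fusionscan
Title: Fusion Gene Detection from Paired-End RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects expressed fusion genes from paired-end RNA-seq reads.
    Discordant read pairs whose mates map uniquely to two different,
    non-adjacent and non-paralogous genes nominate candidate gene pairs; an
    artificial database of all exon-exon junction sequences between each
    candidate pair is then searched with previously unmapped reads to locate
    the exact fusion point, and the pattern of junction-read alignment start
    positions (tiling versus stacked) separates genuine fusion junctions from
    misalignment artifacts. Calls are annotated with reading-frame status,
    RPKM expression, chromosomal class and copy-number association. A
    deterministic synthetic-data generator emits desk-scale genomes,
    annotation, reads and ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
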
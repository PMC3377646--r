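Package: celluminer
Title: Genome Mining of Actinobacterial Cellulose Utilization Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inventorying and classifying cellulolytic enzyme
    systems in annotated high-GC bacterial genomes. Reads GenBank or
    GFF3+FASTA annotation, scans genomes for degenerate palindromic
    operator sites (CelR-like LacI-family repressor sites) within a
    mismatch budget, partitions genes into operons by an intergenic
    distance rule, predicts regulons and cellobiose ABC-transporter
    operons, classifies glycoside hydrolase (GH) family enzymes by
    domain architecture into activity classes, and rediscovers operator
    motifs de novo with a ZOOPS expectation-maximization search. A
    seeded synthetic-genome generator with complete ground truth makes
    every stage verifiable offline.
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
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
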
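Package: dbconcord
Title: Concordance of Microbial Reference Genome Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonizes microbial reference-genome catalogues to NCBI
    taxonomic identifiers at a chosen rank (species or genus), computes
    N-way overlap partitions, exactly-k aggregates, per-database coverage
    and consensus sets, classifies references as complete, fragmented or
    mixed assemblies, and profiles contig length distributions. Includes
    parsers for the NCBI taxdump dialect, a canonical per-sequence
    manifest TSV, NCBI assembly_summary files and FASTA composition
    scans, plus a seeded synthetic-catalogue generator that plants a
    known overlap partition, composition fractions and contig length
    model so the whole pipeline can be validated by ground-truth
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
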
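Package: hicscaff
Title: Chromosome-Scale Genome Scaffolding from Hi-C Contact Data
Version: 0.1.0
Authors@R:
    person("hicscaff", "developers", email = "hicscaff@example.org",
           role = c("aut", "cre"))
Description: Constructs chromosome-scale scaffolds from draft assembly
    contigs and Hi-C read-pair alignments. Contigs are optionally broken
    at positions lacking Hi-C spanning coverage (candidate misassemblies),
    a resolution-chunked contact matrix is built and normalized against an
    expected contact-decay profile estimated from intra-contig cells,
    candidate contig joins are scored in all four orientations, and a
    scaffolding graph is simplified (tip trimming, transitive-edge removal,
    bubble popping, repeat masking, orientation resolution) and traversed
    to scaffold paths over multiple resolution rounds. Includes AGP/FASTA
    output, a seeded Hi-C simulator with full truth provenance, and a
    truth-based evaluator of contiguity and misassembly classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    Rsamtools,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
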
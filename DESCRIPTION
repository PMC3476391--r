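Package: postasm
Title: Post-Assembly Processing of De Novo Pyrosequenced Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analyses that follow de novo assembly
    of a pyrosequenced (454-style) transcriptome: clustering contigs joined
    by broken reads into isogroups (putative genes) and enumerating
    link-supported contig paths as isotigs (putative transcripts);
    consolidating per-isotig homology annotations into a single isogroup
    annotation with synonym collapsing and top-five tie-breaking; assessing
    completeness against a core single-copy gene set by reciprocal best
    alignment; calling expression on a custom microarray against a
    random-probe quantile null with a k-of-n replication rule; and calling
    single-nucleotide variants from read-to-isotig alignments with
    allele-frequency and read-support filters, including cross-isotig
    deduplication and a binomial bound on false calls from sequencing error.
    A synthetic-data module generates inputs with known truth for every
    stage, so the whole pipeline can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
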
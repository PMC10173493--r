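Package: txcomplexity
Title: Transcriptome Complexity Metrics from Genome Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transcript-model complexity from genome annotations in
    GTF format using three per-species metrics (transcripts per gene, exons per
    transcript, unique exons per gene), the Effective Exon Number (a
    Simpson-type effective number of a transcript's exon-length partition)
    compared against a Broken Stick null of uniformly random intron placement,
    partitioning of annotations into ortholog and lineage-specific (novel)
    gene sets from OrthoDB-format flat files, and a rank-based statistical
    battery for comparing whole-transcriptome, ortholog and novel complexity
    distributions within and across species. Includes a synthetic-annotation
    generator emulating multi-species GTFs and OrthoDB tables so the full
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
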
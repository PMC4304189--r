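Package: bidiortho
Title: Orthology Mapping of Bidirectional Promoters Between Two Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates bidirectional promoters (divergent gene pairs whose
    transcription start sites lie within 1,000 bp) from transcript
    annotations in genePred or BED12 form, validates their start sites
    with CAGE peaks and CpG islands, maps each promoter into a second
    genome through UCSC chain/net pairwise alignments restricted to
    level-1 nets, classifies the promoter's state in the second genome
    into five orthology categories, and quantifies co-expression of
    bidirectional pairs within a species and of confirmed orthologs
    across species. Includes a synthetic paired-genome generator with
    full ground truth for benchmarking every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
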
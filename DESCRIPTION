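Package: dualpollen
Title: Dual-Indexed Pollen Meta-Barcoding Toolkit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for highly multiplexed amplicon meta-barcoding of mixed
    pollen samples on the Illumina MiSeq platform. Covers construction and
    quality control of dual-indexed oligo scaffolds (adapter, 8-nt index,
    10-nt pad, 2-nt linker, amplifying primer), exact dual-index
    demultiplexing of paired reads, overlap-based paired-end merging with
    quality filtering, construction of seven-rank taxonomic reference
    databases in RDP-training and UTAX-annotated dialects, a naive Bayes
    k-mer classifier with bootstrap confidence, aggregation of per-read
    assignments into community matrices with rare-taxon and sequencing-depth
    filters, species-accumulation (rarefaction) analysis, and a
    mock-community sequencing-run simulator with known ground truth so the
    whole workflow can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phyloseq,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
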
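Package: seqsubset
Title: Quality-Based Subset Selection of High-Depth Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects subsets of high-depth FASTQ sequencing data for de novo
    genome assembly using base-quality statistics. Implements three read
    scores -- the minimal base quality of a read (MQV), the whole-read
    product of per-base correctness probabilities (ProductQ), and the
    minimum over k-mer windows of the windowed ProductQ -- together with
    the paired-end statistic PE-MQV (the smaller of the two mates' MQVs).
    Provides score distributions with cumulative views, chunked
    computation with deterministic merging, threshold determination from a
    target subset fraction or a target coverage depth, subset filtering
    with FASTA/FASTQ output, k-mer-spectrum genome-size and coverage
    estimation, a seeded synthetic-FASTQ generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
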
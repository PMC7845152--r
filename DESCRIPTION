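Package: readqc
Title: Streaming Quality Control for High-Throughput Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-pass quality control for FASTQ (plain or gzip) and
    SAM files of sequencing reads. One streaming scan of the input
    collects the sufficient statistics for every analysis module
    (per-base and per-sequence Phred quality, base and GC composition,
    N content, length distribution, sequence duplication,
    overrepresented sequences, adapter content and optional k-mer
    enrichment); a postprocessing stage grades each module pass, warn
    or fail against configurable thresholds and writes FastQC-dialect
    text reports ('fastqc_data.txt', 'summary.txt') plus an interactive
    HTML report, so existing downstream report aggregators can consume
    the output unchanged. Includes a deterministic FASTQ fixture
    generator with planted structure and a naive two-pass recomputation
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
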
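# readqc

Streaming quality control for high-throughput sequencing reads, in R.

Quality control is the first step of essentially every sequencing
pipeline: before mapping or assembly, a file of reads is screened for
positional quality decay, biased base composition, unexpected GC
distributions, missing calls, PCR over-amplification, adapter
read-through and contaminating library artifacts. `readqc` performs
that screen in **one streaming pass** over a FASTQ (plain or
gzip-compressed), SAM or BAM file: a single scan collects the
sufficient statistics for every analysis module, and a postprocessing
stage turns them into graded module reports. Because the outputs use
the `fastqc_data.txt` / `summary.txt` dialects that downstream
aggregators already parse, `readqc` drops into existing pipelines
without changes.

## What it computes

For a file of reads, one pass accumulates, per base position *p* and
Phred value *q*: base counts $c_{b,p}$ ($b \in \{A,C,G,T,N\}$) and
quality counts $h_{q,p}$; per read: a GC-percent histogram
($\mathrm{round}(100\,(G{+}C)/\ell)$), a truncated mean-quality
histogram, and a read-length histogram; the earliest match position of
each adapter (full occurrence, or a terminal prefix of at least 12
bases); per-tile quality sums keyed on the flowcell tile parsed from
the read header; and a bounded duplication tracker that stores the
first 100,000 distinct sequences (truncated to 50 bp) and counts every
later occurrence.

Postprocessing derives the standard analysis modules — per-base
quality quartiles (percentile rule: lowest $q$ whose cumulative count
reaches $p\%$ of the column), per-tile quality deviations, per-sequence
quality scores, per-base sequence content, per-sequence GC content
against a fitted normal curve, per-base N content, the length
distribution, sequence duplication levels, overrepresented sequences
(annotated against a contaminant list by exact overlap of ≥ 20 bases
with ≤ 1 mismatch), adapter content, and an optional k-mer module —
and grades each one *pass*, *warn* or *fail* against configurable
thresholds (the packaged defaults; or any FastQC-format limits file).

Counts for sequences that stopped being tracked once the duplication
tracker filled are extrapolated with the closed form

$$\hat{c} \;=\; \frac{c}{1-\prod_{i=0}^{m-1}\frac{T-c-i}{T-i}}$$

where $c$ is the observed duplication level, $m$ the number of reads
seen while the tracker was still accepting new sequences, and $T$ the
total read count.

Memory is bounded by the longest read (statistics matrices) and the
tracker capacity — never by the number of reads.

## Worked example

```r
library(readqc)

# a synthetic library with planted structure: 2,000 reads of 100 bp,
# a 30-copy duplicate, and the universal adapter entering at base 60
# in 12% of reads
spec <- fixture_spec(
  n_reads = 2000, read_len = 100,
  quality = list(type = "gradient", from = 38, to = 30),
  duplicates = 30,
  adapter = list(sequence = "AGATCGGAAGAG", start = 60, fraction = 0.12),
  tiles = c(2101, 2102), seed = 7)
generate_fastq(spec, "example.fq")

rep <- run_qc("example.fq", quiet = TRUE)
print(rep)
#> <qc_report> example.fq
#>   PASS Basic Statistics
#>   PASS Per base sequence quality
#>   PASS Per tile sequence quality
#>   PASS Per sequence quality scores
#>   PASS Per base sequence content
#>   PASS Per sequence GC content
#>   PASS Per base N content
#>   PASS Sequence Length Distribution
#>   PASS Sequence Duplication Levels
#>   FAIL Overrepresented sequences
#>   FAIL Adapter Content
```

The two failures are exactly the planted defects. The 30-copy
duplicate is 1.5% of the library — above the 1% error threshold for
overrepresented sequences (the duplication module itself still passes:
the deduplicated percentage is 98.55%, well above its 70/50
thresholds):

```r
rep$modules[["Overrepresented sequences"]]$rows[, -1]
#>   Count Percentage Possible Source
#> 1    30        1.5          No Hit
```

and the adapter-content curve climbs to 12% of reads from position 60
onward, past the 10% error threshold:

```r
max(rep$modules[["Adapter Content"]]$rows[["Illumina Universal Adapter"]])
#> [1] 12
```

`run_qc()` wrote three files into `example_fastqc/`:
`fastqc_data.txt` (all module tables in the block dialect),
`summary.txt` (one `PASS|WARN|FAIL` line per module) and
`fastqc_report.html` (interactive plots, rendered client-side with
Plotly).

## Command line

```sh
readqc example.fq                  # writes example_fastqc/ next to it
readqc -o out -l my_limits.txt -a my_adapters.txt reads.fq.gz aln.sam
```

Flags mirror the conventional QC tool options (`-o/--outdir`,
`-f/--format`, `-l/--limits`, `-a/--adapters`, `-c/--contaminants`,
`--nogroup`, `-q/--quiet`); unknown flags are warned about and
ignored so the program can stand in for other QC tools inside
pipeline glue.

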
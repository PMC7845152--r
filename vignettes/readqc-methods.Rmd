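---
title: "readqc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{readqc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents how `readqc` computes each quality-control
module, the thresholds and numerical conventions it uses, what the
synthetic fixture generator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed.

## The single-pass design

Conventional QC implementations run each analysis module over every
read, so per-read cost grows with the number of modules and shared
quantities (base identities, quality values) are recomputed several
times. `readqc` instead centralizes reading: one streaming pass over
the input updates a single accumulator holding the *sufficient
statistics* for all modules, and every module is then a pure function
of that accumulator. Re-running postprocessing on the same accumulator
reproduces the report byte for byte.

The accumulator holds, for maximum observed read length $L$:

* `base_counts` — a $5 \times L$ matrix of A/C/G/T/N counts per
  position;
* `qual_counts` — a $94 \times L$ matrix of quality counts per
  position (offset-33 codes 0–93, covering all printable Phred
  characters);
* per-read histograms: GC percent (0–100), truncated mean quality
  (0–93), and read length;
* per-tile quality sums and observation counts per position;
* per-adapter counts of the earliest match position per read;
* a bounded duplication tracker (below);
* optionally, positional 7-mer counts ($4^7 \times (L-6)$).

Memory is therefore proportional to the longest read and the tracker
capacity, and independent of file size. For throughput the parser
hands the accumulator bounded *chunks* of records (the buffer is
capped at roughly $2\times10^6$ buffered bases and shrinks
automatically for long reads) rather than literally one record per
call; `next_record()` exposes the strict one-record interface over the
same parser. The tests assert the measurable contract: processing a
file replicated tenfold leaves tracker size, matrix dimensions and all
per-read-normalized histograms unchanged.

## Input handling

*Formats.* FASTQ is strict 4-line records; multi-line (wrapped)
records are rejected, with errors reporting the offending line number.
Gzip input is detected by extension and, independently, by the
`1f 8b` magic bytes. SAM records contribute name, SEQ and QUAL; header
lines and records with SEQ `*` are skipped; a QUAL of `*` with a
present SEQ is treated as all-`!` (Phred 0) rather than an error, a
robustness choice for pipelines. SAM reads are taken exactly as
stored, with no reverse-complementing by flag: QC describes the stored
bases. BAM is supported through `Rsamtools` when installed; requesting
BAM without it is a fatal, instructive error. Bases are uppercased on
input; anything outside A/C/G/T counts as N in positional statistics.

*Phred encoding.* The lowest quality character across the whole file
decides the encoding: below ASCII 33 is an error; 33–63 is offset 33
("Sanger / Illumina 1.9"); 64 and above is the legacy offset 64. The
single boundary at 64 follows the convention used by FastQC-compatible
tools; codes 59–63 therefore resolve to offset 33. Note the
consequence, visible with synthetic data: a file whose qualities are
uniformly high (no character below `@`) is interpreted as legacy
offset 64, exactly as the emulated tools would.

*Degenerate inputs.* An empty file yields a report with Total
Sequences 0 and only the Basic Statistics module — pipelines get a
parseable report rather than a crash. Zero-length reads are legal;
they contribute to the length histogram (driving that module's fail
grade) and to the duplication tracker, but not to positional or
per-read quality/GC statistics.

## Position binning

Positional tables use one row per base for reads up to 75 bp. Longer
reads keep single-base resolution for positions 1–9 and then bin with
widths that widen with read length (5 beyond position 9; 10 beyond 49
for reads over 200 bp; 50 beyond 99 for reads over 300 bp; 100 beyond
499 for reads over 1000 bp; 500 beyond 999 for reads over 2000 bp),
so the "Base" column matches the labels downstream parsers expect
(`1`…`9`, `10-14`, …). `--nogroup` forces single-base rows at any
length. Groups always tile $1..L$ without gaps or overlap — a
property-style test asserts this across lengths.

## Module definitions and grading

Grading uses *strict* comparisons throughout: a value exactly at a
threshold does not trigger it. The packaged default thresholds (a
`limits`-dialect file under `inst/extdata/`) are the standard defaults
of FastQC-compatible tools; every value can be overridden with
`-l/--limits`.

* **Per base sequence quality.** Per group: mean, median, quartiles,
  10th/90th percentiles from the pooled quality histogram. The
  percentile rule is "lowest quality whose cumulative count reaches
  $p\%$ of the column total" — on the histogram $\{10{:}1, 20{:}1,
  30{:}2\}$ the median is 20. Warn when any lower quartile < 10 or
  median < 25; fail below 5 / 20.
* **Per tile sequence quality.** For each tile × group, the tile's
  mean quality minus the pooled mean over all tile-bearing reads for
  that group. Tile ids come from read names: split on `:`, field 5 of
  7+ fields (Casava 1.8+) or field 3 of 5–6 fields (legacy); files
  without parseable tiles omit the module. Every read is accumulated
  (no subsampling): the simplest contract faithful to the statistics.
  Grade on the deepest drop: warn past 5, fail past 10.
* **Per sequence quality scores.** Histogram of per-read mean quality,
  truncated toward zero. Grade on the mode (ties resolve to the
  lowest value): warn below 27, fail below 20.
* **Per base sequence content.** %A/%C/%G/%T over non-N calls per
  group; groups with no unambiguous calls print zeros and are excluded
  from grading. Grade on $\max(|A-T|, |G-C|)$: warn past 10, fail past
  20 percentage points.
* **Per sequence GC content.** Per-read GC percent is
  $\lfloor 100(G{+}C)/\ell + 0.5\rfloor$ over the full read length
  including N (half-up rounding). The theoretical curve is a normal
  distribution integrated over unit bins, scaled to the read total.
  Its location is a *peak-smoothed mode*: the count-weighted mean of
  the bins holding at least half the peak count. A raw argmax proved
  statistically biased — on a pure binomial GC sample of 4,000 reads,
  single-bin noise in the argmax alone inflates the deviation
  statistic to ~17% — while the smoothed mode tracks the peak and
  still sits uselessly between the peaks of a bimodal library, which
  therefore fails as it should. Scale is the root mean square
  deviation of the histogram around that location. The deviation
  statistic is $100 \sum_i |obs_i - theo_i| / N$: warn past 15, fail
  past 30. The theoretical curve integrates to the read total within
  1% (asserted in tests).
* **Per base N content.** %N per group over all calls; warn past 5,
  fail past 20.
* **Sequence length distribution.** Single row for uniform lengths;
  otherwise bins with a width from {1, 2, 5, 10, 25, …} chosen so at
  most 50 rows appear. Warn when lengths vary; fail when any
  zero-length read exists.
* **Sequence duplication levels.** The tracker stores the first
  100,000 distinct sequences (longer sequences truncated to their
  first 50 bp, so a 250 bp read and its re-sequenced twin still
  collide) and counts every later occurrence of a tracked sequence.
  `count_at_limit` is the number of reads seen while the tracker was
  still accepting new sequences — it advances on *every* read until
  the tracker freezes, so when the tracker never fills it equals the
  total and the extrapolation below is exact. Observed level counts
  are corrected by $\hat c = c / (1 - \prod_{i=0}^{m-1}
  (T-c-i)/(T-i))$, levels are collated into the conventional 16 bins
  (1–9, `>10`, `>50`, …, `>10k`), and the report carries two series
  (percent of deduplicated, percent of total) plus the Total
  Deduplicated Percentage $= 100 \sum \hat c_{\text{distinct}} /
  \sum \hat c \cdot \text{level}$. Warn when that percentage drops
  below 70, fail below 50.
* **Overrepresented sequences.** Tracked sequences above 0.1% of
  reads, sorted by count, each annotated with the best contaminant
  sharing an exact overlap of ≥ 20 bases with at most one mismatch
  (both strands considered), else "No Hit". The packaged contaminant
  list is a curated set of widely published Illumina adapter/primer
  sequences; `-c` substitutes any list in the same dialect. Warn when
  anything exceeds 0.1%, fail past 1%.
* **Adapter content.** A read matches an adapter at position $p$ when
  the adapter (or, if the read ends first, an adapter prefix of at
  least 12 bases) occurs at $p$; only the earliest $p$ counts. The
  curve is cumulative: $100 \times$ (reads matched at or before $p$) /
  (reads of length ≥ $p$), averaged within base groups for display and
  truncated where a 12-base seed no longer fits. Warn past 5%, fail
  past 10%.
* **Kmer content** (disabled by default in the limits). Positional
  7-mer counts against a uniform expectation from each 7-mer's overall
  frequency, scored with a one-sided binomial tail probability,
  Bonferroni-corrected over every k-mer × position cell tested —
  without that correction the sheer number of cells (~10^5) flags
  uniform random libraries. Reported k-mers are those with corrected
  $p < 0.01$, ranked by $p$ then count; grading reads the limits
  thresholds (2 / 5) as $-\log_{10} p$.

## Report dialects

`fastqc_data.txt` opens with a `##FastQC<TAB>0.11.8` marker — emitted
deliberately, because downstream parsers dispatch on that magic line —
followed by one `>>Title<TAB>grade` block per module with a
`#`-prefixed header row, tab-separated data rows, and `>>END_MODULE`.
Numbers print with up to 10 significant digits, trailing zeros
trimmed; there are no timestamps, so reruns are byte-identical.
`summary.txt` is `PASS|WARN|FAIL<TAB>Module Title<TAB>filename`. The
HTML report embeds the module data as JSON and renders interactive
plots client-side with the Plotly library, referenced by CDN URL by
default to keep the three outputs small (about 0.02 MB for a
100,000-read file, against a 1 MB budget); `plotly = "none"` writes a
fully offline, plot-free page, and a local plotly.js path can be
inlined instead.

## The fixture generator and what passing tests mean

`fixture_spec()`/`generate_fastq()` produce deterministic FASTQ with
planted truths: fixed or ranged read lengths; constant, gradient or
per-tile quality profiles; uniform, biased or mixture base
composition (the mixture giving bimodal GC); planted duplicate
sequences at exact multiplicities; a planted adapter at a fixed
position in a chosen fraction of reads; N injection; tile-structured
Casava headers; zero-length reads. The manifest records the planted
counts exactly, and `two_pass_oracle()` recomputes every accumulator
field definitionally (whole file in memory, per-read code) for
equivalence testing.

The generator emulates what the QC modules *measure*, not sequencing
itself: no position-dependent error model, no quality–base-call
correlation, no optical duplicates, no paired-end structure. Passing
tests therefore demonstrate that the statistics, grades and dialects
are computed correctly on data with known structure — not that any
particular real library would pass or fail.

Test problem sizes are deliberately modest — boundary fixtures of
300–4,000 reads at 50–100 bp, oracle-equivalence sweeps over a dozen
randomized specs, one 100,000 × 150 bp run for the footprint check —
sizes at which every planted effect is far from its grading threshold
relative to sampling noise (margins of 4σ or more), so grade
expectations are stable under the fixed seeds.

## Known limitations

* Paired-end files are processed independently; there is no joint
  mate handling.
* FASTA input, quality trimming and read filtering are out of scope.
* `-t/--threads` is accepted for compatibility but processing is
  sequential; single-file throughput (~15k reads/s at 150 bp) is
  adequate for QC of bounded inputs, not for multi-hundred-GB
  archives.
* The per-tile module accumulates every read; on files with very many
  tiles and very long reads its memory grows with tiles × length.
* The k-mer statistic is intentionally conservative (Bonferroni); it
  will miss weak positional enrichment that a targeted motif tool
  would find.
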
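lim <- load_limits()
cont <- load_contaminants()

report_of <- function(st, ...) qc_report(st, limits = lim,
                                         contaminants = cont, ...)

module_from <- function(st, title, ...) {
  report_of(st, ...)$modules[[title]]
}

test_that("percentile rule: lowest value whose cumulative count reaches p", {
  h <- numeric(94)
  h[c(10, 20) + 1] <- 1
  h[30 + 1] <- 2
  expect_equal(readqc:::hist_percentile(h, 0:93, 50), 20)
  expect_equal(readqc:::hist_percentile(h, 0:93, 25), 10)
  expect_equal(readqc:::hist_percentile(h, 0:93, 90), 30)
})

test_that("per-base quality: degenerate histogram and grade boundaries", {
  # all qualities 30 -> every statistic 30, pass
  st <- stats_from_reads(rep("ACGT", 5), rep("????", 5))  # '?' = 63 -> q30
  m <- module_from(st, "Per base sequence quality")
  expect_equal(unique(unlist(m$rows[-1])), 30)
  expect_equal(m$grade, "pass")

  # median 22 at every position -> warn (below 25, above 20)
  st <- stats_from_reads(rep("ACGT", 5), rep("7777", 5))  # '7' = 55 -> q22
  expect_equal(module_from(st, "Per base sequence quality")$grade, "warn")

  # median 17 -> fail (below 20)
  st <- stats_from_reads(rep("ACGT", 5), rep("2222", 5))  # '2' = 50 -> q17
  expect_equal(module_from(st, "Per base sequence quality")$grade, "fail")
})

test_that("per-tile quality: deviations from the pooled mean drive grade", {
  # one tile only: all deviations 0, pass
  st <- stats_from_reads(rep("ACGT", 4), rep("????", 4),
                         name = sprintf("I:1:F:1:2101:%d:1", 1:4))
  m <- module_from(st, "Per tile sequence quality")
  expect_equal(unique(m$rows$Mean), 0)
  expect_equal(m$grade, "pass")

  # two tiles, B uniformly 12 below A: deviations +/-6 -> warn at 5/10
  nm <- sprintf("I:1:F:1:%d:%d:1", rep(c(2101, 2102), each = 4), 1:8)
  ql <- rep(c("????", "3333"), each = 4)   # q30 vs q18
  st <- stats_from_reads(rep("ACGT", 8), ql, name = nm)
  m <- module_from(st, "Per tile sequence quality")
  expect_equal(sort(unique(m$rows$Mean)), c(-6, 6))
  expect_equal(m$grade, "warn")

  # 24 apart -> deviation -12 -> fail
  ql <- rep(c("IIII", "++++"), each = 4)   # q40 vs q10
  st <- stats_from_reads(rep("ACGT", 8), ql, name = nm)
  expect_equal(module_from(st, "Per tile sequence quality")$grade, "fail")

  # headerless names: module absent from the report
  st <- stats_from_reads(rep("ACGT", 4), rep("????", 4),
                         name = paste0("read_", 1:4))
  expect_null(module_from(st, "Per tile sequence quality"))
})

test_that("per-sequence quality grades on the modal mean quality", {
  # '?EEK' = Phred 30,36,36,42: mean 36, lowest char stays in Sanger range
  st <- stats_from_reads(rep("ACGT", 6), rep("?EEK", 6))
  m <- module_from(st, "Per sequence quality scores")
  expect_equal(m$rows$Quality, 36)
  expect_equal(m$rows$Count, 6)
  expect_equal(m$grade, "pass")

  st <- stats_from_reads(rep("ACGT", 6), rep("3333", 6))  # q18 -> fail
  expect_equal(module_from(st, "Per sequence quality scores")$grade, "fail")

  # bimodal with the mode at 35 ('D' = q35 six times, q18 four) -> pass
  st <- stats_from_reads(rep("ACGT", 10),
                         c(rep("DDDD", 6), rep("3333", 4)))
  m <- module_from(st, "Per sequence quality scores")
  expect_equal(m$grade, "pass")
  expect_equal(m$rows$Quality[which.max(m$rows$Count)], 35)
})

test_that("per-base content: balance, poly-A, and all-N groups", {
  # four rotated reads: exactly 25% each base at every position
  reads <- c("ACGT", "CGTA", "GTAC", "TACG")
  st <- stats_from_reads(reads, rep("????", 4))
  m <- module_from(st, "Per base sequence content")
  expect_true(all(abs(as.matrix(m$rows[, c("G", "A", "T", "C")]) - 25)
                  < 1e-9))
  expect_equal(m$grade, "pass")
  expect_equal(names(m$rows), c("Base", "G", "A", "T", "C"))

  # poly-A: |A - T| = 100 -> fail
  st <- stats_from_reads(rep("AAAA", 4), rep("????", 4))
  expect_equal(module_from(st, "Per base sequence content")$grade, "fail")

  # a position with only N calls is reported as 0 and not graded
  st <- stats_from_reads(rep("ACGN", 4), rep("????", 4))
  m <- module_from(st, "Per base sequence content")
  expect_equal(unlist(m$rows[4, c("G", "A", "T", "C")]), rep(0, 4),
               ignore_attr = TRUE)
})

test_that("per-sequence GC: 101 rows, normal fit, deviation grading", {
  # tight unimodal at scale: deviation below warn threshold
  spec <- fixture_spec(n_reads = 4000, read_len = 100, quality = 30,
                       seed = 21)
  fq <- tempfile(fileext = ".fq")
  generate_fastq(spec, fq)
  m <- module_from(qc_collect(fq), "Per sequence GC content")
  expect_equal(nrow(m$rows), 101L)
  expect_equal(m$rows$`GC Content`, 0:100)
  # theoretical curve integrates to the read total within 1%
  expect_lt(abs(sum(m$extra$theoretical) - 4000) / 4000, 0.01)
  expect_equal(m$grade, "pass")

  # strongly bimodal mixture -> fail
  spec <- fixture_spec(
    n_reads = 800, read_len = 100, quality = 30,
    base_probs = list(probs = list(c(.35, .15, .15, .35),
                                   c(.15, .35, .35, .15)),
                      weights = c(.5, .5)), seed = 22)
  generate_fastq(spec, fq)
  expect_equal(module_from(qc_collect(fq),
                           "Per sequence GC content")$grade, "fail")

  # single read: curve degenerate but the module still emits 101 rows
  st <- stats_from_reads("ACGT", "IIII")
  m <- module_from(st, "Per sequence GC content")
  expect_equal(nrow(m$rows), 101L)
})

test_that("per-base N content uses reads reaching each position", {
  st <- stats_from_reads(rep("ACGT", 4), rep("????", 4))
  m <- module_from(st, "Per base N content")
  expect_equal(m$rows$`N-Count`, rep(0, 4))
  expect_equal(m$grade, "pass")

  # 30% N at one position -> fail at 5/20
  reads <- c(rep("ACNT", 3), rep("ACGT", 7))
  st <- stats_from_reads(reads, rep("????", 10))
  m <- module_from(st, "Per base N content")
  expect_equal(m$rows$`N-Count`[3], 30)
  expect_equal(m$grade, "fail")

  # N only in the last position of the longest reads: denominator is
  # the count of reads reaching that position
  reads <- c("ACGTN", "ACGTN", "ACG", "ACG", "ACG", "ACG")
  st <- stats_from_reads(reads, c("?????", "?????", rep("???", 4)))
  m <- module_from(st, "Per base N content")
  expect_equal(m$rows$`N-Count`[5], 100)   # 2 N out of 2 reads at pos 5
})

test_that("length distribution: uniform, variable, zero-length", {
  st <- stats_from_reads(rep(strrep("A", 100), 3),
                         rep(strrep("?", 100), 3))
  m <- module_from(st, "Sequence Length Distribution")
  expect_equal(m$rows$Length, "100")
  expect_equal(m$rows$Count, 3)
  expect_equal(m$grade, "pass")

  st <- stats_from_reads(c(strrep("A", 99), strrep("A", 100)),
                         c(strrep("?", 99), strrep("?", 100)))
  m <- module_from(st, "Sequence Length Distribution")
  expect_equal(m$grade, "warn")
  expect_equal(sum(m$rows$Count), 2)

  st <- stats_from_reads(c("", "ACGT"), c("", "????"))
  expect_equal(module_from(st, "Sequence Length Distribution")$grade,
               "fail")
})

test_that("duplication levels: dedup percentage and binning", {
  # X x3 + Y x1 -> 2 distinct / 4 total = 50.0, fail at 70/50? no: 50
  # is not < 50 (strict), so warn
  X <- strrep("ACGT", 10); Y <- strrep("TTCA", 10)
  st <- stats_from_reads(c(X, X, X, Y), rep(strrep("?", 40), 4))
  m <- module_from(st, "Sequence Duplication Levels")
  expect_equal(m$extra$total_deduplicated_percentage, 50)
  expect_equal(m$grade, "warn")
  expect_equal(m$rows$`Duplication Level`,
               c(as.character(1:9), ">10", ">50", ">100", ">500",
                 ">1k", ">5k", ">10k"))
  # level-1 and level-3 slots each hold one of two distinct sequences
  expect_equal(m$rows$`Percentage of deduplicated`[c(1, 3)], c(50, 50))
  expect_equal(m$rows$`Percentage of total`[c(1, 3)], c(25, 75))

  # all reads distinct, tracker not full -> 100, pass
  spec <- fixture_spec(n_reads = 50, read_len = 40, seed = 31)
  fq <- tempfile(fileext = ".fq")
  generate_fastq(spec, fq)
  m <- module_from(qc_collect(fq), "Sequence Duplication Levels")
  expect_equal(m$extra$total_deduplicated_percentage, 100)
  expect_equal(m$grade, "pass")

  # one sequence at 60% of reads -> dedup far below 50 -> fail
  spec <- fixture_spec(n_reads = 200, read_len = 40, duplicates = 120,
                       seed = 32)
  generate_fastq(spec, fq)
  m <- module_from(qc_collect(fq), "Sequence Duplication Levels")
  expect_lt(m$extra$total_deduplicated_percentage, 50)
  expect_equal(m$grade, "fail")
})

test_that("overrepresented sequences: listing threshold, sources, grade", {
  # a sequence at 1.5% of 1000 reads -> listed and fail (> 1%)
  spec <- fixture_spec(n_reads = 1000, read_len = 50, duplicates = 15,
                       seed = 33)
  fq <- tempfile(fileext = ".fq")
  man <- generate_fastq(spec, fq)
  m <- module_from(qc_collect(fq), "Overrepresented sequences")
  expect_equal(m$rows$Sequence[1], man$duplicates$sequence[1])
  expect_equal(m$rows$Count[1], 15)
  expect_equal(m$rows$Percentage[1], 1.5)
  expect_equal(m$grade, "fail")

  # nothing above 0.1%: empty table, pass
  spec <- fixture_spec(n_reads = 1200, read_len = 50, seed = 34)
  generate_fastq(spec, fq)
  m <- module_from(qc_collect(fq), "Overrepresented sequences")
  expect_equal(nrow(m$rows), 0L)
  expect_equal(m$grade, "pass")

  # planted contaminant prefix is annotated with the contaminant name
  cseq <- substr(cont$sequence[cont$name == "Nextera Transposase Sequence Read 1"], 1, 33)
  spec <- fixture_spec(n_reads = 300, read_len = 50, duplicates = 9,
                       duplicate_sequences = paste0(cseq,
                                                    strrep("A", 17)),
                       seed = 35)
  generate_fastq(spec, fq)
  m <- module_from(qc_collect(fq), "Overrepresented sequences")
  expect_equal(m$grade, "fail")
  expect_match(m$rows$`Possible Source`[1], "Nextera Transposase")
})

test_that("contaminant overlap rule: >= 20 bases, at most one mismatch", {
  conts <- data.frame(name = "C1",
                      sequence = "ACGTACGTACGTACGTACGTACGT",
                      stringsAsFactors = FALSE)
  # exact 24-base containment
  s <- paste0("TTTTT", conts$sequence, "GGGGG")
  expect_match(readqc:::contaminant_source(s, conts), "C1 \\(100% over 24bp\\)")
  # one mismatch in the middle still matches over the full stretch
  s2 <- s
  substr(s2, 17, 17) <- "C"   # mutate inside the contaminant region
  expect_match(readqc:::contaminant_source(s2, conts), "C1")
  # only a 15-base overlap: below the 20-base floor
  s3 <- paste0(substr(conts$sequence, 1, 15), strrep("T", 30))
  expect_equal(readqc:::contaminant_source(s3, conts), "No Hit")
})

test_that("adapter content: cumulative percentages and grading", {
  # no adapters present: all zeros, pass
  spec <- fixture_spec(n_reads = 200, read_len = 60, seed = 36)
  fq <- tempfile(fileext = ".fq")
  generate_fastq(spec, fq)
  m <- module_from(qc_collect(fq), "Adapter Content")
  expect_true(all(as.matrix(m$rows[, -1]) == 0))
  expect_equal(m$grade, "pass")

  # 20% of reads with the adapter from position 30: curve steps to ~20
  spec <- fixture_spec(n_reads = 500, read_len = 60,
                       adapter = list(sequence = "AGATCGGAAGAG",
                                      start = 30, fraction = 0.2),
                       seed = 37)
  man <- generate_fastq(spec, fq)
  m <- module_from(qc_collect(fq), "Adapter Content")
  ua <- m$rows[["Illumina Universal Adapter"]]
  expect_lt(max(ua[m$rows$Position < 30]), 1)
  planted_pct <- 100 * man$adapter$n_reads_with / 500
  expect_equal(max(ua), planted_pct, tolerance = 0.01)
  expect_equal(m$grade, "fail")

  # adapter only at the very end: nonzero only in the last groups
  spec <- fixture_spec(n_reads = 300, read_len = 60,
                       adapter = list(sequence = "AGATCGGAAGAG",
                                      start = 49, fraction = 0.3),
                       seed = 38)
  generate_fastq(spec, fq)
  m <- module_from(qc_collect(fq), "Adapter Content")
  ua <- m$rows[["Illumina Universal Adapter"]]
  expect_equal(max(ua[m$rows$Position < 49]), 0)
  expect_gt(ua[length(ua)], 25)
})

test_that("k-mer module is absent by default and flags planted 7-mers", {
  spec <- fixture_spec(n_reads = 400, read_len = 50,
                       adapter = list(sequence = "GATTACAGATTACA",
                                      start = 20, fraction = 0.5),
                       seed = 39)
  fq <- tempfile(fileext = ".fq")
  generate_fastq(spec, fq)

  # default limits disable the module entirely
  rep_def <- qc_report(qc_collect(fq), limits = lim, contaminants = cont)
  expect_false("Kmer Content" %in% names(rep_def$modules))

  # enabled: the planted 7-mer tops the table at its fixed offset
  lim2 <- lim
  lim2$kmer$ignore <- 0
  st <- qc_collect(fq, kmer = TRUE)
  m <- qc_report(st, limits = lim2, contaminants = cont)$
    modules[["Kmer Content"]]
  expect_gt(nrow(m$rows), 0L)
  # the top-ranked k-mer is one of the planted adapter's 7-mers, and
  # the repeated GATTACA itself is flagged
  planted_kmers <- unique(substring("GATTACAGATTACA", 1:8, 7:14))
  expect_true(m$rows$Sequence[1] %in% planted_kmers)
  expect_true("GATTACA" %in% m$rows$Sequence)
  expect_equal(m$grade, "fail")

  # uniform random reads: nothing flagged
  spec <- fixture_spec(n_reads = 300, read_len = 50, seed = 40)
  generate_fastq(spec, fq)
  st <- qc_collect(fq, kmer = TRUE)
  m <- qc_report(st, limits = lim2, contaminants = cont)$
    modules[["Kmer Content"]]
  expect_equal(m$grade, "pass")
})

test_that("grade(): strict threshold comparisons in both directions", {
  expect_equal(grade(4, 10, 5, "low"), "fail")
  expect_equal(grade(7, 10, 5, "low"), "warn")
  expect_equal(grade(10, 10, 5, "low"), "pass")   # exactly at warn
  expect_equal(grade(5, 10, 5, "low"), "warn")    # exactly at error
  expect_equal(grade(11, 5, 10, "high"), "fail")
  expect_equal(grade(10, 5, 10, "high"), "warn")
  expect_equal(grade(5, 5, 10, "high"), "pass")
})

test_that("basic statistics rows and empty-input report", {
  st <- stats_from_reads(rep("ACGT", 4), rep("IIII", 4))
  st$filename <- "x.fq"
  m <- module_from(st, "Basic Statistics")
  v <- stats::setNames(m$rows$Value, m$rows$Measure)
  expect_equal(v[["Total Sequences"]], "4")
  expect_equal(v[["Sequence length"]], "4")
  expect_equal(v[["%GC"]], "50")
  expect_equal(v[["Sequences flagged as poor quality"]], "0")
  expect_equal(m$grade, "pass")

  # empty input: Total Sequences 0, data-dependent modules skipped
  fq <- tempfile(fileext = ".fq")
  file.create(fq)
  rep0 <- qc_report(qc_collect(fq), limits = lim, contaminants = cont)
  expect_equal(names(rep0$modules), "Basic Statistics")
  v <- stats::setNames(rep0$modules[[1]]$rows$Value,
                       rep0$modules[[1]]$rows$Measure)
  expect_equal(v[["Total Sequences"]], "0")
  expect_equal(v[["Sequence length"]], "0")
})

test_that("module tables are pure functions of the accumulator", {
  spec <- fixture_spec(n_reads = 150, read_len = 60, tiles = c(1, 2),
                       duplicates = 10, n_rate = 0.01, seed = 41)
  fq <- tempfile(fileext = ".fq")
  generate_fastq(spec, fq)
  st <- qc_collect(fq)
  r1 <- qc_report(st, limits = lim, contaminants = cont)
  r2 <- qc_report(st, limits = lim, contaminants = cont)
  expect_identical(write_qc_data(r1), write_qc_data(r2))
})
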
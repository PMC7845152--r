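# The single-pass collector. One streaming scan of the input updates
# every sufficient statistic needed by the analysis modules: per-position
# base and quality histograms, per-read GC / mean-quality / length
# histograms, the bounded duplication tracker, per-tile quality sums and
# per-adapter earliest-match counters. Postprocessing (see modules.R)
# never touches the reads again.

BASE_LUT <- local({
  x <- rep.int(5L, 127L)          # anything not A/C/G/T counts as N
  x[utf8ToInt("A")] <- 1L
  x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L
  x[utf8ToInt("T")] <- 4L
  x
})

QUAL_BINS <- 94L                   # offset-33 Phred values 0..93
DUP_TRACK_PREFIX <- 50L            # tracked sequences truncated to 50 bp
ADAPTER_MIN_SEED <- 12L            # minimum adapter prefix matched at read end

#' Create an empty accumulator of streaming read statistics
#'
#' Usually called through [qc_collect()]; exposed so that statistics can
#' be accumulated record by record with [update_stats()].
#'
#' @param filename Display name of the input (used in reports).
#' @param format Input format label.
#' @param adapters Adapter data frame (see [load_adapters()]).
#' @param dup_capacity Maximum number of distinct (truncated) sequences
#'   tracked for the duplication and overrepresentation modules.
#' @param kmer Logical; also collect positional 7-mer counts (off by
#'   default, matching the default limits which disable the k-mer
#'   module).
#' @return A `qc_stats` environment.
#' @export
new_qc_stats <- function(filename = "reads", format = "fastq",
                         adapters = load_adapters(),
                         dup_capacity = 100000L, kmer = FALSE) {
  st <- new.env(parent = emptyenv())
  st$filename <- filename
  st$format <- format
  st$n_reads <- 0L
  st$max_len <- 0L
  st$min_len <- NA_integer_
  st$min_qchar <- Inf
  st$base_counts <- matrix(
    0, nrow = 5L, ncol = 0L,
    dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  st$qual_counts <- matrix(0, nrow = QUAL_BINS, ncol = 0L)
  st$len_hist <- numeric(1L)       # index i = count of reads of length i-1
  st$gc_hist <- numeric(101L)      # GC percent 0..100
  st$meanq_hist <- numeric(QUAL_BINS)
  st$dup <- new_dup_tracker(dup_capacity)
  st$tiles <- new.env(hash = TRUE, parent = emptyenv())
  st$has_tiles <- FALSE
  st$adapters <- adapters
  st$adapter_first <- matrix(0, nrow = nrow(adapters), ncol = 0L,
                             dimnames = list(adapters$name, NULL))
  st$kmer_on <- isTRUE(kmer)
  st$kmer_k <- 7L
  st$kmer_counts <- if (st$kmer_on) {
    matrix(0, nrow = 4L^7L, ncol = 0L)
  } else NULL
  st$encoding <- NULL
  class(st) <- "qc_stats"
  st
}

grow_cols <- function(m, ncol_new) {
  if (ncol(m) >= ncol_new) return(m)
  out <- matrix(0, nrow = nrow(m), ncol = ncol_new,
                dimnames = list(rownames(m), NULL))
  if (ncol(m) > 0L) out[, seq_len(ncol(m))] <- m
  out
}

pad_codes <- function(s, L) {
  v <- utf8ToInt(s)
  length(v) <- L
  v
}

#' Update streaming statistics with a batch of reads
#'
#' The core accumulation step: every histogram in `stats` is incremented
#' exactly once per read. Vectorised over records, so a single record or
#' a whole chunk can be passed. Reads are expected uppercased with
#' quality strings the same length as the bases (the readers in this
#' package guarantee both); per-read GC percent is `round(100 * (G+C) /
#' length)` over the full read length including N, mean read quality is
#' binned by truncation toward zero, and zero-length reads contribute
#' only to the length histogram (and the duplication tracker).
#'
#' @param stats A `qc_stats` accumulator from [new_qc_stats()].
#' @param bases Character vector of read sequences.
#' @param quality Character vector of quality strings.
#' @param name Optional character vector of read names (needed for the
#'   per-tile module).
#' @return `stats`, invisibly (the accumulator is modified in place).
#' @export
update_stats <- function(stats, bases, quality, name = NULL) {
  n <- length(bases)
  if (n == 0L) return(invisible(stats))
  if (length(quality) != n) {
    stop("bases and quality must have the same length", call. = FALSE)
  }
  lens <- nchar(bases)
  if (any(nchar(quality) != lens)) {
    stop("quality string length differs from read length", call. = FALSE)
  }

  # read-length histogram (index 1 = zero-length reads)
  L <- max(lens)
  if (length(stats$len_hist) < L + 1L) {
    lh <- numeric(L + 1L)
    lh[seq_along(stats$len_hist)] <- stats$len_hist
    stats$len_hist <- lh
  }
  stats$len_hist <- stats$len_hist + tabulate(lens + 1L,
                                              nbins = length(stats$len_hist))
  stats$min_len <- min(stats$min_len, lens, na.rm = TRUE)
  stats$max_len <- max(stats$max_len, L)

  pos_reads <- lens > 0L
  if (any(pos_reads)) {
    sq <- bases[pos_reads]
    ql <- quality[pos_reads]
    l2 <- lens[pos_reads]
    Lc <- max(l2)
    stats$base_counts <- grow_cols(stats$base_counts, Lc)
    stats$qual_counts <- grow_cols(stats$qual_counts, Lc)
    stats$adapter_first <- grow_cols(stats$adapter_first, Lc)

    Bc <- vapply(sq, pad_codes, integer(Lc), L = Lc, USE.NAMES = FALSE)
    Qc <- vapply(ql, pad_codes, integer(Lc), L = Lc, USE.NAMES = FALSE)
    if (Lc == 1L) { Bc <- rbind(Bc); Qc <- rbind(Qc) }
    valid <- !is.na(Qc)
    pm <- row(Qc)

    # per-position base counts
    Bi <- matrix(BASE_LUT[Bc], nrow = nrow(Bc))
    bidx <- Bi[valid] + 5L * (pm[valid] - 1L)
    stats$base_counts[, seq_len(Lc)] <- stats$base_counts[, seq_len(Lc)] +
      matrix(tabulate(bidx, nbins = 5L * Lc), nrow = 5L)

    # per-position quality histograms (offset-33 bins)
    stats$min_qchar <- min(stats$min_qchar, Qc[valid])
    q33 <- Qc - 33L
    qv <- q33[valid]
    qv[qv > QUAL_BINS - 1L] <- QUAL_BINS - 1L
    qidx <- qv + 1L + QUAL_BINS * (pm[valid] - 1L)
    stats$qual_counts[, seq_len(Lc)] <- stats$qual_counts[, seq_len(Lc)] +
      matrix(tabulate(qidx, nbins = QUAL_BINS * Lc), nrow = QUAL_BINS)

    # per-read GC percent (denominator = full read length, incl. N)
    gc_cnt <- colSums(Bi == 2L | Bi == 3L, na.rm = TRUE)
    gp <- as.integer(floor(100 * gc_cnt / l2 + 0.5))
    stats$gc_hist <- stats$gc_hist + tabulate(gp + 1L, nbins = 101L)

    # per-read mean quality, truncated toward zero
    mq <- as.integer(colSums(q33, na.rm = TRUE) %/% l2)
    mq[mq > QUAL_BINS - 1L] <- QUAL_BINS - 1L
    mq[mq < 0L] <- 0L
    stats$meanq_hist <- stats$meanq_hist + tabulate(mq + 1L, nbins = QUAL_BINS)

    # per-tile quality sums
    if (!is.null(name)) {
      tiles <- tile_from_name(name[pos_reads])
      has <- !is.na(tiles)
      if (any(has)) {
        stats$has_tiles <- TRUE
        q33z <- q33
        q33z[!valid] <- 0L
        for (tl in unique(tiles[has])) {
          idx <- which(has & tiles == tl)
          key <- as.character(tl)
          ent <- stats$tiles[[key]]
          if (is.null(ent)) {
            ent <- list(qsum = numeric(Lc), n = numeric(Lc))
          } else if (length(ent$qsum) < Lc) {
            length(ent$qsum) <- Lc
            length(ent$n) <- Lc
            ent$qsum[is.na(ent$qsum)] <- 0
            ent$n[is.na(ent$n)] <- 0
          }
          ent$qsum[seq_len(Lc)] <- ent$qsum[seq_len(Lc)] +
            rowSums(q33z[, idx, drop = FALSE])
          ent$n[seq_len(Lc)] <- ent$n[seq_len(Lc)] +
            rowSums(valid[, idx, drop = FALSE])
          stats$tiles[[key]] <- ent
        }
      }
    }

    # earliest adapter match per read
    if (nrow(stats$adapters) > 0L) {
      fp <- scan_adapters(sq, stats$adapters, lens = l2)
      for (j in seq_len(nrow(stats$adapters))) {
        pj <- fp[, j]
        pj <- pj[!is.na(pj)]
        if (length(pj)) {
          stats$adapter_first[j, seq_len(Lc)] <-
            stats$adapter_first[j, seq_len(Lc)] + tabulate(pj, nbins = Lc)
        }
      }
    }

    # positional 7-mer counts (only when the k-mer module is enabled)
    if (stats$kmer_on) {
      k <- stats$kmer_k
      if (Lc >= k) {
        stats$kmer_counts <- grow_cols(stats$kmer_counts, Lc - k + 1L)
        dig <- chartr("ACGT", "0123", sq)
        for (p in seq_len(Lc - k + 1L)) {
          ok <- l2 >= p + k - 1L
          if (!any(ok)) next
          val <- suppressWarnings(
            strtoi(substr(dig[ok], p, p + k - 1L), base = 4L))
          val <- val[!is.na(val)]   # windows containing non-ACGT dropped
          if (length(val)) {
            stats$kmer_counts[, p] <- stats$kmer_counts[, p] +
              tabulate(val + 1L, nbins = 4L^k)
          }
        }
      }
    }
  }

  # duplication tracker (order-dependent; includes zero-length reads)
  keys <- paste0("s", substr(bases, 1L, DUP_TRACK_PREFIX))
  r0 <- stats$n_reads
  for (i in seq_len(n)) {
    track_duplication(stats$dup, keys[i], r0 + i, raw_key = TRUE)
  }

  stats$n_reads <- stats$n_reads + n
  invisible(stats)
}

## ---- duplication tracker ---------------------------------------------

#' Create a bounded duplication tracker
#'
#' Tracks the first `capacity` distinct sequences (truncated to 50 bp)
#' seen in the stream and counts every later occurrence of a tracked
#' sequence. `count_at_limit` records how many reads had been seen while
#' the tracker was still accepting new sequences; it is the basis of the
#' extrapolation in [corrected_count()].
#'
#' @param capacity Maximum number of distinct sequences tracked
#'   (default 100000).
#' @return A `dup_tracker` environment.
#' @export
new_dup_tracker <- function(capacity = 100000L) {
  tr <- new.env(parent = emptyenv())
  tr$counts <- new.env(hash = TRUE, parent = emptyenv())
  tr$capacity <- as.integer(capacity)
  tr$size <- 0L
  tr$frozen <- FALSE
  tr$count_at_limit <- 0L
  tr$total_reads <- 0L
  class(tr) <- "dup_tracker"
  tr
}

#' Feed one read to the duplication tracker
#'
#' Sequences longer than 50 bases are truncated to their first 50 bases
#' before tracking. A tracked sequence has its count incremented; an
#' unseen sequence is inserted only while fewer than `capacity` distinct
#' sequences are stored, after which the tracker is frozen and new
#' sequences are ignored (their occurrences are extrapolated later via
#' [corrected_count()]).
#'
#' @param tracker A tracker from [new_dup_tracker()].
#' @param bases The read sequence.
#' @param reads_seen 1-based index of this read in the stream.
#' @param raw_key Internal: `bases` is already a prepared tracker key.
#' @return The tracker, invisibly.
#' @export
track_duplication <- function(tracker, bases, reads_seen, raw_key = FALSE) {
  k <- if (raw_key) bases else paste0("s", substr(bases, 1L, DUP_TRACK_PREFIX))
  if (!tracker$frozen) tracker$count_at_limit <- as.integer(reads_seen)
  e <- tracker$counts
  cur <- e[[k]]
  if (!is.null(cur)) {
    e[[k]] <- cur + 1L
  } else if (!tracker$frozen) {
    e[[k]] <- 1L
    tracker$size <- tracker$size + 1L
    if (tracker$size >= tracker$capacity) tracker$frozen <- TRUE
  }
  tracker$total_reads <- as.integer(reads_seen)
  invisible(tracker)
}

dup_table <- function(tracker) {
  keys <- ls(tracker$counts, sorted = FALSE)
  if (length(keys) == 0L) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  cnt <- vapply(keys, function(k) tracker$counts[[k]], integer(1),
                USE.NAMES = FALSE)
  data.frame(sequence = substring(keys, 2L), count = cnt,
             stringsAsFactors = FALSE)
}

#' Extrapolate a full-library count from a bounded tracker
#'
#' A sequence observed `observed` times among sequences tracked from the
#' first `count_at_limit` reads of a file of `total` reads is scaled up
#' by the probability that a sequence of that duplication level entered
#' the tracker at all:
#' `observed / (1 - prod_{i=0}^{count_at_limit-1} (total-observed-i)/(total-i))`.
#' When the tracker saw the whole file (`count_at_limit == total`) or the
#' product would be degenerate (`total - observed < count_at_limit`) the
#' observed count is already exact.
#'
#' @param observed Observed duplication level (>= 1).
#' @param count_at_limit Reads seen while the tracker was still
#'   accepting new sequences.
#' @param total Total reads in the file.
#' @return The corrected (extrapolated) count, a double.
#' @examples
#' corrected_count(2, 2, 4)  # 2.4
#' @export
corrected_count <- function(observed, count_at_limit, total) {
  if (total == 0) stop("total read count is zero", call. = FALSE)
  if (count_at_limit == total) return(as.numeric(observed))
  if (total - observed < count_at_limit) return(as.numeric(observed))
  i <- 0:(count_at_limit - 1)
  p_not_seen <- prod((total - observed - i) / (total - i))
  observed / (1 - p_not_seen)
}

## ---- adapter scanning -------------------------------------------------

#' Earliest adapter match position per read
#'
#' For each read and each adapter, finds the earliest 1-based position
#' at which the adapter sequence occurs -- or, when the read ends before
#' the adapter is complete, at which a prefix of the adapter of at least
#' 12 bases runs to the end of the read.
#'
#' @param bases Character vector of read sequences (uppercase).
#' @param adapters Adapter data frame (see [load_adapters()]).
#' @param lens Optional precomputed `nchar(bases)`.
#' @return Integer matrix, reads x adapters; `NA` where an adapter does
#'   not occur.
#' @export
scan_adapters <- function(bases, adapters, lens = nchar(bases)) {
  out <- matrix(NA_integer_, nrow = length(bases), ncol = nrow(adapters),
                dimnames = list(NULL, adapters$name))
  for (j in seq_len(nrow(adapters))) {
    a <- adapters$sequence[j]
    p <- regexpr(a, bases, fixed = TRUE, useBytes = TRUE)
    p <- ifelse(p < 0L, NA_integer_, as.integer(p))
    alen <- nchar(a)
    if (alen > ADAPTER_MIN_SEED) {
      for (k in seq.int(alen - 1L, ADAPTER_MIN_SEED)) {
        pref <- substr(a, 1L, k)
        hit <- lens >= k & substr(bases, lens - k + 1L, lens) == pref
        cand <- ifelse(hit, lens - k + 1L, NA_integer_)
        p <- pmin(p, cand, na.rm = TRUE)
      }
      p[is.nan(p)] <- NA_integer_
    }
    out[, j] <- p
  }
  out
}

## ---- tile parsing -----------------------------------------------------

#' Extract the flowcell tile id from a read name
#'
#' Splits the name on `:`; names with 7 or more fields use the 5th field
#' (Casava 1.8+ headers), names with 5 or 6 fields use the 3rd (legacy
#' Illumina headers). Anything else, or a non-numeric candidate field,
#' yields `NA`.
#'
#' @param name Character vector of read names.
#' @return Integer vector of tile ids (`NA` where none can be parsed).
#' @examples
#' tile_from_name("M001:1:FC:1:2101:5:9")        # 2101
#' tile_from_name("HWUSI:6:73:941:1973#0/1")     # 73
#' tile_from_name("read_1")                      # NA
#' @export
tile_from_name <- function(name) {
  parts <- strsplit(name, ":", fixed = TRUE)
  vapply(parts, function(p) {
    np <- length(p)
    cand <- if (np >= 7L) p[5L] else if (np >= 5L) p[3L] else
      return(NA_integer_)
    suppressWarnings(as.integer(cand))
  }, integer(1L))
}

## ---- base grouping ----------------------------------------------------

#' Group read positions into the bins used for positional statistics
#'
#' Short reads (75 bases or fewer) get one group per position. Longer
#' reads keep single-base groups for the first 9 positions, then switch
#' to fixed-width bins whose width widens with read length (5 beyond
#' position 9; 10 beyond position 49 for reads over 200 bases; 50 beyond
#' position 99 for reads over 300; and so on), so positional tables stay
#' readable at any read length. `nogroup` forces single-base groups
#' throughout.
#'
#' @param max_len Longest read length in the file.
#' @param nogroup Disable binning entirely.
#' @return Data frame with columns `start`, `end`, `label`; groups tile
#'   `1..max_len` without gaps or overlap.
#' @examples
#' make_base_groups(5)$label
#' head(make_base_groups(150)$label, 12)
#' @export
make_base_groups <- function(max_len, nogroup = FALSE) {
  max_len <- as.integer(max_len)
  if (is.na(max_len) || max_len < 1L) {
    stop("max_len must be a positive integer", call. = FALSE)
  }
  if (nogroup || max_len <= 75L) {
    p <- seq_len(max_len)
    return(data.frame(start = p, end = p, label = as.character(p),
                      stringsAsFactors = FALSE))
  }
  starts <- ends <- integer(0)
  start <- 1L
  interval <- 1L
  while (start <= max_len) {
    end <- min(start + interval - 1L, max_len)
    starts <- c(starts, start)
    ends <- c(ends, end)
    start <- start + interval
    if (start == 10L && max_len > 75L) interval <- 5L
    if (start == 50L && max_len > 200L) interval <- 10L
    if (start == 100L && max_len > 300L) interval <- 50L
    if (start == 500L && max_len > 1000L) interval <- 100L
    if (start == 1000L && max_len > 2000L) interval <- 500L
  }
  data.frame(
    start = starts, end = ends,
    label = ifelse(starts == ends, as.character(starts),
                   paste0(starts, "-", ends)),
    stringsAsFactors = FALSE)
}

## ---- driver -----------------------------------------------------------

#' Collect streaming statistics from a sequencing file
#'
#' Runs the single pass over the input: opens the stream, accumulates
#' every sufficient statistic chunk by chunk, detects the Phred encoding
#' from the lowest quality character seen, and returns the accumulator.
#' Memory is bounded by the chunk buffer (adapted to read length), never
#' by the number of reads.
#'
#' @param path Input file (FASTQ, gzip FASTQ, SAM or BAM).
#' @param format Optional format override, see [open_reads()].
#' @param adapters Adapter data frame (default: packaged list).
#' @param dup_capacity Duplication tracker capacity.
#' @param kmer Also collect positional 7-mer counts.
#' @param chunk_size Reads parsed per buffer; shrunk automatically for
#'   long reads so buffered data stays bounded.
#' @return A `qc_stats` object.
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' st <- qc_collect(fq)
#' st$n_reads
#' @export
qc_collect <- function(path, format = NULL, adapters = load_adapters(),
                       dup_capacity = 100000L, kmer = FALSE,
                       chunk_size = 5000L) {
  stream <- open_reads(path, format)
  on.exit(close_reads(stream))
  st <- new_qc_stats(filename = basename(path), format = stream$format,
                     adapters = adapters, dup_capacity = dup_capacity,
                     kmer = kmer)
  n <- min(chunk_size, 500L)   # small first chunk to learn read length
  repeat {
    ch <- read_chunk(stream, n)
    if (is.null(ch)) break
    update_stats(st, ch$bases, ch$quality, ch$name)
    n <- max(50L, min(chunk_size,
                      as.integer(ceiling(2e6 / max(1L, st$max_len)))))
  }
  st$encoding <- detect_encoding(
    if (is.finite(st$min_qchar)) st$min_qchar else 33L)
  st
}

#' @export
print.qc_stats <- function(x, ...) {
  cat("<qc_stats> ", x$filename, " (", x$format, ")\n",
      "  reads: ", x$n_reads,
      "  length: ", if (is.na(x$min_len)) "-" else
        if (x$min_len == x$max_len) x$max_len else
          paste0(x$min_len, "-", x$max_len),
      "\n  tracked sequences: ", x$dup$size,
      if (x$dup$frozen) " (tracker full)" else "", "\n", sep = "")
  if (!is.null(x$encoding)) cat("  encoding:", x$encoding$label, "\n")
  invisible(x)
}
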
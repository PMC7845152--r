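# Deterministic synthetic FASTQ generation with planted structure, and
# a naive two-pass oracle that recomputes every collected statistic by
# definition. Together they make every analysis module testable with no
# external data.

#' Describe a synthetic FASTQ fixture
#'
#' Builds a validated specification for [generate_fastq()]. All
#' randomness is driven by `seed`, so the same spec always produces a
#' byte-identical file.
#'
#' @param n_reads Number of regular reads.
#' @param read_len Read length: a single value, or `c(min, max)` for
#'   lengths drawn uniformly from that range.
#' @param quality Per-position quality model: a single Phred value
#'   (constant), `list(type = "gradient", from =, to =)` for a linear
#'   profile across the read, or `list(type = "tile_offset", base =,
#'   offsets = c("2101" = 0, ...))` for per-tile offsets.
#' @param base_probs Base composition: `NULL` for uniform A/C/G/T,
#'   a length-4 probability vector in A,C,G,T order, or
#'   `list(probs = list(p1, p2, ...), weights = ...)` for a per-read
#'   mixture (e.g. a bimodal GC distribution).
#' @param duplicates Integer vector of planted duplicate multiplicities;
#'   each entry m plants one sequence occurring exactly m times, spread
#'   through the file.
#' @param duplicate_sequences Optional character vector parallel to
#'   `duplicates` giving the planted sequences themselves (`NA` entries
#'   are drawn at random). Useful to plant a known contaminant.
#' @param adapter `list(sequence =, start =, fraction =)`: plant
#'   `sequence` starting at 1-based `start` in a `fraction` of reads.
#' @param tiles Integer vector of tile ids assigned round-robin (read
#'   names then carry Casava-style 7-field headers); `NULL` gives plain
#'   names with no tile information.
#' @param n_rate Per-base probability of replacing a call with N.
#' @param n_position Restrict N injection to this single position.
#' @param zero_length Number of zero-length reads appended at the end.
#' @param seed Integer seed fixing all randomness.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_reads, read_len = 100L, quality = 35,
                         base_probs = NULL, duplicates = NULL,
                         duplicate_sequences = NULL,
                         adapter = NULL, tiles = NULL, n_rate = 0,
                         n_position = NULL, zero_length = 0L, seed = 1L) {
  stopifnot(n_reads >= 1, length(read_len) %in% c(1L, 2L),
            all(read_len >= 1), n_rate >= 0, n_rate <= 1,
            zero_length >= 0)
  if (is.numeric(quality) && length(quality) == 1L) {
    quality <- list(type = "constant", value = quality)
  }
  stopifnot(is.list(quality), quality$type %in%
              c("constant", "gradient", "tile_offset"))
  if (quality$type == "tile_offset" && is.null(tiles)) {
    stop("tile_offset quality model requires tile ids", call. = FALSE)
  }
  if (!is.null(base_probs) && is.numeric(base_probs)) {
    stopifnot(length(base_probs) == 4L)
    base_probs <- list(probs = list(base_probs / sum(base_probs)),
                       weights = 1)
  }
  min_len <- min(read_len)
  if (!is.null(adapter)) {
    stopifnot(is.list(adapter), !is.null(adapter$sequence),
              adapter$fraction >= 0, adapter$fraction <= 1)
    if (adapter$start + nchar(adapter$sequence) - 1L > min_len) {
      stop("planted adapter does not fit in the shortest read",
           call. = FALSE)
    }
  }
  if (!is.null(duplicates)) {
    duplicates <- as.integer(duplicates)
    stopifnot(all(duplicates >= 1), sum(duplicates) <= n_reads)
    if (!is.null(duplicate_sequences)) {
      stopifnot(length(duplicate_sequences) == length(duplicates))
      ok <- is.na(duplicate_sequences) |
        (grepl("^[ACGT]+$", duplicate_sequences) &
           nchar(duplicate_sequences) <= min_len)
      if (!all(ok)) {
        stop("duplicate_sequences must be A/C/G/T and fit in the ",
             "shortest read", call. = FALSE)
      }
    }
  }
  structure(list(n_reads = as.integer(n_reads),
                 read_len = as.integer(read_len), quality = quality,
                 base_probs = base_probs, duplicates = duplicates,
                 duplicate_sequences = duplicate_sequences,
                 adapter = adapter, tiles = tiles, n_rate = n_rate,
                 n_position = n_position,
                 zero_length = as.integer(zero_length),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_fixture_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

quality_string <- function(model, len, tile = NA, max_len = len) {
  if (len == 0L) return("")
  q <- switch(model$type,
    constant = rep(model$value, len),
    gradient = round(model$from + (model$to - model$from) *
                       (seq_len(len) - 1L) / max(1L, max_len - 1L)),
    tile_offset = {
      off <- model$offsets[[as.character(tile)]]
      if (is.null(off) || is.na(off)) off <- 0
      rep(model$base + off, len)
    })
  q <- pmin(pmax(round(q), 0L), 93L)
  intToUtf8(q + 33L)
}

#' Generate a synthetic FASTQ file with planted structure
#'
#' Writes a strict 4-line FASTQ file (gzip-compressed when `path` ends
#' in `.gz`) realising a [fixture_spec()], and returns a manifest of the
#' planted truths: exact duplicate multiplicities, the indices of
#' adapter-bearing reads, per-position injected N counts and the tile
#' assignment. The same spec yields a byte-identical file every time.
#'
#' @param spec A [fixture_spec()].
#' @param path Output FASTQ path.
#' @param manifest_path Optional path for a JSON copy of the manifest.
#' @return The manifest, invisibly.
#' @export
generate_fastq <- function(spec, path, manifest_path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed, {
    n <- spec$n_reads
    lens <- if (length(spec$read_len) == 1L) rep(spec$read_len, n) else
      sample(spec$read_len[1L]:spec$read_len[2L], n, replace = TRUE)
    max_len <- max(lens)
    tiles <- if (!is.null(spec$tiles)) rep_len(spec$tiles, n) else NULL

    # allocate read indices for planted structure, spread through file
    pool <- seq_len(n)
    take_spread <- function(pool, m) {
      sel <- pool[unique(round(seq(1L, length(pool), length.out = m)))]
      if (length(sel) < m) sel <- pool[seq_len(m)]
      sel
    }
    dup_idx <- list()
    dup_seqs <- character(0)
    if (!is.null(spec$duplicates)) {
      for (di in seq_along(spec$duplicates)) {
        m <- spec$duplicates[di]
        sel <- take_spread(pool, m)
        pool <- setdiff(pool, sel)
        given <- spec$duplicate_sequences[di]
        dseq <- if (!is.null(spec$duplicate_sequences) && !is.na(given)) {
          lens[sel] <- nchar(given)
          given
        } else {
          dlen <- min(lens[sel])
          lens[sel] <- dlen
          paste(sample(c("A", "C", "G", "T"), dlen, replace = TRUE),
                collapse = "")
        }
        dup_idx[[di]] <- sel
        dup_seqs[di] <- dseq
      }
    }
    adp_idx <- integer(0)
    if (!is.null(spec$adapter) && spec$adapter$fraction > 0) {
      k <- round(spec$adapter$fraction * n)
      elig <- pool[lens[pool] >=
                     spec$adapter$start + nchar(spec$adapter$sequence) - 1L]
      if (k > length(elig)) k <- length(elig)
      adp_idx <- sort(sample(elig, k))
      pool <- setdiff(pool, adp_idx)
    }

    # draw bases; mixture component per read when requested
    comp <- if (!is.null(spec$base_probs)) {
      sample(seq_along(spec$base_probs$probs), n, replace = TRUE,
             prob = spec$base_probs$weights)
    } else rep(1L, n)
    letters4 <- c("A", "C", "G", "T")
    draw_read <- function(len, ci) {
      if (is.null(spec$base_probs)) {
        paste(sample(letters4, len, replace = TRUE), collapse = "")
      } else {
        paste(sample(letters4, len, replace = TRUE,
                     prob = spec$base_probs$probs[[ci]]), collapse = "")
      }
    }
    bases <- vapply(seq_len(n), function(i) draw_read(lens[i], comp[i]), "")

    # plant duplicates verbatim (duplicate reads are never modified)
    protected <- logical(n)
    for (di in seq_along(dup_idx)) {
      bases[dup_idx[[di]]] <- dup_seqs[di]
      protected[dup_idx[[di]]] <- TRUE
    }
    # plant the adapter
    if (length(adp_idx)) {
      a <- toupper(spec$adapter$sequence)
      s <- spec$adapter$start
      tmp <- bases[adp_idx]
      substr(tmp, s, s + nchar(a) - 1L) <- a
      bases[adp_idx] <- tmp
    }
    # inject N calls (never into planted duplicates)
    n_counts <- numeric(max_len)
    if (spec$n_rate > 0) {
      for (i in which(!protected)) {
        if (!is.null(spec$n_position)) {
          p <- spec$n_position
          if (p <= lens[i] && stats::runif(1) < spec$n_rate) {
            substr(bases[i], p, p) <- "N"
            n_counts[p] <- n_counts[p] + 1
          }
        } else {
          hit <- which(stats::runif(lens[i]) < spec$n_rate)
          if (length(hit)) {
            b <- strsplit(bases[i], "", fixed = TRUE)[[1L]]
            b[hit] <- "N"
            bases[i] <- paste(b, collapse = "")
            n_counts[hit] <- n_counts[hit] + 1
          }
        }
      }
    }

    # qualities and names
    quals <- vapply(seq_len(n), function(i) {
      quality_string(spec$quality, lens[i],
                     tile = if (is.null(tiles)) NA else tiles[i],
                     max_len = max_len)
    }, "")
    names_ <- if (is.null(tiles)) {
      sprintf("read_%d", seq_len(n))
    } else {
      sprintf("SIM:1:FC1:1:%d:%d:1", tiles, seq_len(n))
    }
    if (spec$zero_length > 0L) {
      zn <- sprintf("read_empty_%d", seq_len(spec$zero_length))
      names_ <- c(names_, zn)
      bases <- c(bases, rep("", spec$zero_length))
      quals <- c(quals, rep("", spec$zero_length))
    }

    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else
      file(path, "wb")
    writeLines(as.vector(rbind(paste0("@", names_), bases, "+", quals)),
               con, sep = "\n")
    close(con)

    manifest <- list(
      n_reads = length(bases),
      n_regular = n,
      read_lengths = as.list(table(nchar(bases))),
      duplicates = if (length(dup_seqs)) {
        data.frame(sequence = dup_seqs,
                   times = vapply(dup_idx, length, integer(1)),
                   stringsAsFactors = FALSE)
      } else NULL,
      adapter = if (length(adp_idx)) {
        list(sequence = toupper(spec$adapter$sequence),
             start = spec$adapter$start, n_reads_with = length(adp_idx),
             indices = adp_idx)
      } else NULL,
      n_injected = n_counts,
      tiles = if (is.null(tiles)) NULL else as.list(table(tiles)),
      zero_length = spec$zero_length,
      seed = spec$seed)
    if (!is.null(manifest_path)) {
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA)
    }
    invisible(manifest)
  })
}

## ---- naive two-pass oracle -------------------------------------------

# earliest adapter position in one read, by direct definition
oracle_adapter_pos <- function(read, len, aseq) {
  alen <- nchar(aseq)
  if (len < ADAPTER_MIN_SEED) return(NA_integer_)
  p <- seq_len(len)
  tail_len <- len - p + 1L
  full <- substring(read, p, p + alen - 1L) == aseq
  partial <- tail_len >= ADAPTER_MIN_SEED & tail_len < alen &
    substring(read, p, len) == substr(rep(aseq, len), 1L, tail_len)
  hit <- which(full | partial)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Recompute all streaming statistics naively (two passes, no shortcuts)
#'
#' Loads every read (one record at a time through the same parser the
#' collector uses) and recomputes every accumulator field by its
#' definition with straightforward per-read code: no chunked tabulation,
#' no vectorised position bookkeeping. Used to validate the single-pass
#' collector on small files.
#'
#' @param path Input reads file.
#' @param adapters Adapter data frame.
#' @param dup_capacity Duplication tracker capacity.
#' @return A plain list mirroring the `qc_stats` fields.
#' @export
two_pass_oracle <- function(path, adapters = load_adapters(),
                            dup_capacity = 100000L) {
  stream <- open_reads(path)
  on.exit(close_reads(stream))
  recs <- list()
  repeat {
    r <- next_record(stream)
    if (is.null(r)) break
    recs[[length(recs) + 1L]] <- r
  }
  n <- length(recs)
  lens <- vapply(recs, function(r) nchar(r$bases), integer(1))
  max_len <- if (n) max(lens) else 0L

  base_counts <- matrix(0, 5L, max_len,
                        dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  qual_counts <- matrix(0, 94L, max_len)
  len_hist <- numeric(max_len + 1L)
  gc_hist <- numeric(101L)
  meanq_hist <- numeric(94L)
  min_qchar <- Inf
  tiles <- list()
  adapter_first <- matrix(0, nrow(adapters), max_len,
                          dimnames = list(adapters$name, NULL))
  dup_counts <- new.env(hash = TRUE, parent = emptyenv())
  dup_size <- 0L
  dup_frozen <- FALSE
  dup_cal <- 0L

  for (i in seq_len(n)) {
    r <- recs[[i]]
    len <- lens[i]
    len_hist[len + 1L] <- len_hist[len + 1L] + 1
    if (!dup_frozen) dup_cal <- i
    key <- paste0("s", substr(r$bases, 1L, 50L))
    cur <- dup_counts[[key]]
    if (!is.null(cur)) {
      dup_counts[[key]] <- cur + 1L
    } else if (!dup_frozen) {
      dup_counts[[key]] <- 1L
      dup_size <- dup_size + 1L
      if (dup_size >= dup_capacity) dup_frozen <- TRUE
    }
    if (len == 0L) next

    bi <- BASE_LUT[utf8ToInt(r$bases)]
    q <- utf8ToInt(r$quality)
    min_qchar <- min(min_qchar, q)
    q33 <- pmin(q - 33L, 93L)
    base_counts[cbind(bi, seq_len(len))] <-
      base_counts[cbind(bi, seq_len(len))] + 1
    qual_counts[cbind(q33 + 1L, seq_len(len))] <-
      qual_counts[cbind(q33 + 1L, seq_len(len))] + 1
    gc <- as.integer(floor(100 * sum(bi == 2L | bi == 3L) / len + 0.5))
    gc_hist[gc + 1L] <- gc_hist[gc + 1L] + 1
    mq <- as.integer(sum(q33) %/% len)
    meanq_hist[mq + 1L] <- meanq_hist[mq + 1L] + 1

    tl <- tile_from_name(r$name)
    if (!is.na(tl)) {
      key <- as.character(tl)
      if (is.null(tiles[[key]])) {
        tiles[[key]] <- list(qsum = numeric(max_len), n = numeric(max_len))
      }
      tiles[[key]]$qsum[seq_len(len)] <- tiles[[key]]$qsum[seq_len(len)] + q33
      tiles[[key]]$n[seq_len(len)] <- tiles[[key]]$n[seq_len(len)] + 1
    }
    for (j in seq_len(nrow(adapters))) {
      p <- oracle_adapter_pos(r$bases, len, adapters$sequence[j])
      if (!is.na(p)) adapter_first[j, p] <- adapter_first[j, p] + 1
    }
  }

  keys <- ls(dup_counts, sorted = FALSE)
  dup_tab <- data.frame(
    sequence = substring(keys, 2L),
    count = vapply(keys, function(k) dup_counts[[k]], integer(1),
                   USE.NAMES = FALSE),
    stringsAsFactors = FALSE)

  list(n_reads = n, max_len = max_len,
       min_len = if (n) min(lens) else NA_integer_,
       base_counts = base_counts, qual_counts = qual_counts,
       len_hist = len_hist, gc_hist = gc_hist, meanq_hist = meanq_hist,
       min_qchar = min_qchar,
       dup = list(table = dup_tab, count_at_limit = dup_cal,
                  size = dup_size, frozen = dup_frozen),
       tiles = tiles, adapter_first = adapter_first,
       encoding = detect_encoding(
         if (is.finite(min_qchar)) min_qchar else 33L))
}
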
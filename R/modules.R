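# Postprocessing: turn the collected StreamStats into graded analysis
# modules. Every function here is a pure function of the accumulator --
# rebuilding a report from the same stats yields identical tables.

MODULE_TITLES <- c(
  basic            = "Basic Statistics",
  per_base_quality = "Per base sequence quality",
  per_tile         = "Per tile sequence quality",
  per_seq_quality  = "Per sequence quality scores",
  per_base_content = "Per base sequence content",
  per_seq_gc       = "Per sequence GC content",
  per_base_n       = "Per base N content",
  length_dist      = "Sequence Length Distribution",
  duplication      = "Sequence Duplication Levels",
  overrepresented  = "Overrepresented sequences",
  adapter          = "Adapter Content",
  kmer             = "Kmer Content"
)

MODULE_LIMIT_KEYS <- c(
  basic            = NA,
  per_base_quality = "quality_base",
  per_tile         = "tile",
  per_seq_quality  = "quality_sequence",
  per_base_content = "sequence",
  per_seq_gc       = "gc_sequence",
  per_base_n       = "n_content",
  length_dist      = "sequence_length",
  duplication      = "duplication",
  overrepresented  = "overrepresented",
  adapter          = "adapter",
  kmer             = "kmer"
)

DUP_LABELS <- c(as.character(1:9), ">10", ">50", ">100", ">500",
                ">1k", ">5k", ">10k")

new_module <- function(key, grade, header, rows, extra = list()) {
  structure(list(name = unname(MODULE_TITLES[key]), key = key,
                 grade = grade, header = header, rows = rows,
                 extra = extra),
            class = "qc_module")
}

#' @export
print.qc_module <- function(x, ...) {
  cat(">>", x$name, "\t", x$grade, "  (", nrow(x$rows), " rows)\n", sep = "")
  invisible(x)
}

#' Grade a module statistic against warn/error thresholds
#'
#' Strict comparisons: a value exactly at a threshold does not trigger
#' it. `direction` states which side is bad: `"high"` grades large
#' values as bad (e.g. N content), `"low"` grades small values as bad
#' (e.g. deduplicated percentage).
#'
#' @param value The module's summary statistic.
#' @param warn_threshold,error_threshold Thresholds from the limits.
#' @param direction `"high"` or `"low"`.
#' @return `"pass"`, `"warn"` or `"fail"`.
#' @examples
#' grade(4, 10, 5, "low")   # fail
#' grade(7, 10, 5, "low")   # warn
#' grade(10, 10, 5, "low")  # pass (strict)
#' @export
grade <- function(value, warn_threshold, error_threshold,
                  direction = c("high", "low")) {
  direction <- match.arg(direction)
  past <- if (direction == "high") {
    function(v, t) !is.na(t) && v > t
  } else {
    function(v, t) !is.na(t) && v < t
  }
  if (past(value, error_threshold)) "fail"
  else if (past(value, warn_threshold)) "warn"
  else "pass"
}

worst_grade <- function(grades) {
  if ("fail" %in% grades) "fail" else if ("warn" %in% grades) "warn"
  else "pass"
}

# lowest value whose cumulative count reaches p percent of the histogram
hist_percentile <- function(counts, values, p) {
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  values[which(cumsum(counts) >= p / 100 * tot)[1L]]
}

group_cols <- function(groups, i) seq.int(groups$start[i], groups$end[i])

## ---- individual modules ----------------------------------------------

basic_statistics <- function(stats) {
  bc <- stats$base_counts
  acgt <- if (ncol(bc)) sum(bc[c("A", "C", "G", "T"), ]) else 0
  gc <- if (ncol(bc)) sum(bc[c("C", "G"), ]) else 0
  pct_gc <- if (acgt > 0) as.integer(floor(100 * gc / acgt + 0.5)) else 0L
  len_txt <- if (stats$n_reads == 0L) "0"
    else if (stats$min_len == stats$max_len) as.character(stats$max_len)
    else paste0(stats$min_len, "-", stats$max_len)
  rows <- data.frame(
    Measure = c("Filename", "File type", "Encoding", "Total Sequences",
                "Sequences flagged as poor quality", "Sequence length",
                "%GC"),
    Value = c(stats$filename, "Conventional base calls",
              if (is.null(stats$encoding)) "Sanger / Illumina 1.9"
                else stats$encoding$label,
              as.character(stats$n_reads), "0", len_txt,
              as.character(pct_gc)),
    stringsAsFactors = FALSE)
  new_module("basic", "pass", c("Measure", "Value"), rows)
}

per_base_quality <- function(stats, limits, groups) {
  shift <- stats$encoding$offset - 33L
  vals <- 0:(nrow(stats$qual_counts) - 1L) - shift
  ng <- nrow(groups)
  out <- data.frame(Base = groups$label, Mean = numeric(ng),
                    Median = numeric(ng), `Lower Quartile` = numeric(ng),
                    `Upper Quartile` = numeric(ng),
                    `10th Percentile` = numeric(ng),
                    `90th Percentile` = numeric(ng),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(ng)) {
    h <- rowSums(stats$qual_counts[, group_cols(groups, i), drop = FALSE])
    out$Mean[i] <- sum(vals * h) / sum(h)
    out$Median[i] <- hist_percentile(h, vals, 50)
    out$`Lower Quartile`[i] <- hist_percentile(h, vals, 25)
    out$`Upper Quartile`[i] <- hist_percentile(h, vals, 75)
    out$`10th Percentile`[i] <- hist_percentile(h, vals, 10)
    out$`90th Percentile`[i] <- hist_percentile(h, vals, 90)
  }
  g <- worst_grade(c(
    grade(min(out$`Lower Quartile`),
          limit_value(limits, "quality_base_lower", "warn"),
          limit_value(limits, "quality_base_lower", "error"), "low"),
    grade(min(out$Median),
          limit_value(limits, "quality_base_median", "warn"),
          limit_value(limits, "quality_base_median", "error"), "low")))
  new_module("per_base_quality", g, names(out), out)
}

per_tile_quality <- function(stats, limits, groups) {
  keys <- ls(stats$tiles, sorted = FALSE)
  if (length(keys) == 0L) return(NULL)
  ids <- sort(as.integer(keys))
  L <- stats$max_len
  ng <- nrow(groups)
  qsum_all <- numeric(L)
  n_all <- numeric(L)
  per_tile <- matrix(NA_real_, nrow = length(ids), ncol = ng)
  getv <- function(v) { length(v) <- L; v[is.na(v)] <- 0; v }
  tile_q <- lapply(as.character(ids), function(k) {
    ent <- stats$tiles[[k]]
    list(qsum = getv(ent$qsum), n = getv(ent$n))
  })
  for (tq in tile_q) {
    qsum_all <- qsum_all + tq$qsum
    n_all <- n_all + tq$n
  }
  for (t in seq_along(ids)) {
    for (i in seq_len(ng)) {
      cols <- group_cols(groups, i)
      nt <- sum(tile_q[[t]]$n[cols])
      if (nt > 0 && sum(n_all[cols]) > 0) {
        per_tile[t, i] <- sum(tile_q[[t]]$qsum[cols]) / nt -
          sum(qsum_all[cols]) / sum(n_all[cols])
      }
    }
  }
  rows <- data.frame(
    Tile = rep(ids, each = ng),
    Base = rep(groups$label, times = length(ids)),
    Mean = as.vector(t(per_tile)),
    stringsAsFactors = FALSE)
  rows <- rows[!is.na(rows$Mean), , drop = FALSE]
  worst <- -min(per_tile, na.rm = TRUE)   # magnitude of deepest drop
  g <- grade(worst, limit_value(limits, "tile", "warn"),
             limit_value(limits, "tile", "error"), "high")
  new_module("per_tile", g, c("Tile", "Base", "Mean"), rows)
}

per_sequence_quality <- function(stats, limits) {
  shift <- stats$encoding$offset - 33L
  h <- stats$meanq_hist
  vals <- 0:(length(h) - 1L) - shift
  nz <- which(h > 0)
  rng <- seq.int(min(nz), max(nz))
  rows <- data.frame(Quality = vals[rng], Count = h[rng],
                     stringsAsFactors = FALSE)
  mode_q <- vals[which.max(h)]
  g <- grade(mode_q, limit_value(limits, "quality_sequence", "warn"),
             limit_value(limits, "quality_sequence", "error"), "low")
  new_module("per_seq_quality", g, c("Quality", "Count"), rows)
}

per_base_content <- function(stats, limits, groups) {
  ng <- nrow(groups)
  pct <- matrix(0, nrow = ng, ncol = 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  gradable <- logical(ng)
  for (i in seq_len(ng)) {
    cnt <- rowSums(stats$base_counts[, group_cols(groups, i), drop = FALSE])
    tot <- sum(cnt[c("A", "C", "G", "T")])
    if (tot > 0) {
      pct[i, ] <- 100 * cnt[c("A", "C", "G", "T")] / tot
      gradable[i] <- TRUE
    }
  }
  rows <- data.frame(Base = groups$label, G = pct[, "G"], A = pct[, "A"],
                     T = pct[, "T"], C = pct[, "C"],
                     check.names = FALSE, stringsAsFactors = FALSE)
  if (any(gradable)) {
    dev <- max(abs(pct[gradable, "A"] - pct[gradable, "T"]),
               abs(pct[gradable, "G"] - pct[gradable, "C"]))
    g <- grade(dev, limit_value(limits, "sequence", "warn"),
               limit_value(limits, "sequence", "error"), "high")
  } else g <- "pass"
  new_module("per_base_content", g, names(rows), rows)
}

# theoretical curve: normal centred on the histogram's smoothed mode
# (count-weighted mean of the bins within half of the peak height;
# robust to single-bin sampling noise in the argmax) with spread
# estimated from the mass around that centre, integrated over unit bins
gc_theoretical <- function(obs) {
  tot <- sum(obs)
  x <- 0:100
  peak <- which(obs >= max(obs) / 2)
  mode <- sum(x[peak] * obs[peak]) / sum(obs[peak])
  sd <- sqrt(sum(obs * (x - mode)^2) / tot)
  if (sd < 1e-9) {
    theo <- ifelse(x == mode, tot, 0)
  } else {
    theo <- tot * (stats::pnorm(x + 0.5, mode, sd) -
                   stats::pnorm(x - 0.5, mode, sd))
  }
  theo
}

per_sequence_gc <- function(stats, limits) {
  obs <- stats$gc_hist
  tot <- sum(obs)
  theo <- gc_theoretical(obs)
  deviation <- 100 * sum(abs(obs - theo)) / tot
  rows <- data.frame(`GC Content` = 0:100, Count = obs,
                     check.names = FALSE, stringsAsFactors = FALSE)
  g <- grade(deviation, limit_value(limits, "gc_sequence", "warn"),
             limit_value(limits, "gc_sequence", "error"), "high")
  new_module("per_seq_gc", g, c("GC Content", "Count"), rows,
             extra = list(theoretical = theo, deviation = deviation))
}

per_base_n <- function(stats, limits, groups) {
  ng <- nrow(groups)
  pct <- numeric(ng)
  for (i in seq_len(ng)) {
    cnt <- rowSums(stats$base_counts[, group_cols(groups, i), drop = FALSE])
    tot <- sum(cnt)
    pct[i] <- if (tot > 0) 100 * cnt["N"] / tot else 0
  }
  rows <- data.frame(Base = groups$label, `N-Count` = pct,
                     check.names = FALSE, stringsAsFactors = FALSE)
  g <- grade(max(pct), limit_value(limits, "n_content", "warn"),
             limit_value(limits, "n_content", "error"), "high")
  new_module("per_base_n", g, names(rows), rows)
}

length_bins <- function(min_len, max_len) {
  if (min_len == max_len) {
    return(data.frame(start = min_len, end = min_len,
                      label = as.character(min_len),
                      stringsAsFactors = FALSE))
  }
  span <- max_len - min_len + 1L
  widths <- c(1L, 2L, 5L, 10L, 25L, 50L, 100L, 250L, 500L, 1000L,
              2500L, 5000L, 10000L, 25000L, 50000L, 100000L)
  w <- widths[which(ceiling(span / widths) <= 50L)[1L]]
  if (is.na(w)) w <- widths[length(widths)]
  start <- (min_len %/% w) * w
  starts <- seq.int(start, max_len, by = w)
  ends <- pmin(starts + w - 1L, rep(.Machine$integer.max, length(starts)))
  data.frame(
    start = starts, end = ends,
    label = if (w == 1L) as.character(starts)
            else paste0(starts, "-", ends),
    stringsAsFactors = FALSE)
}

length_distribution <- function(stats, limits) {
  h <- stats$len_hist                    # index i = length i-1
  bins <- length_bins(stats$min_len, stats$max_len)
  counts <- vapply(seq_len(nrow(bins)), function(i) {
    lo <- bins$start[i]; hi <- min(bins$end[i], stats$max_len)
    if (hi < lo) 0 else sum(h[(lo:hi) + 1L])
  }, numeric(1))
  rows <- data.frame(Length = bins$label, Count = counts,
                     stringsAsFactors = FALSE)
  zero_len <- h[1L] > 0
  g <- "pass"
  if (limit_value(limits, "sequence_length", "warn", 1) == 1 &&
      stats$min_len != stats$max_len) g <- "warn"
  if (limit_value(limits, "sequence_length", "error", 1) == 1 && zero_len)
    g <- "fail"
  new_module("length_dist", g, c("Length", "Count"), rows)
}

dup_slot <- function(level) {
  ifelse(level <= 9, level,
  ifelse(level < 50, 10L,
  ifelse(level < 100, 11L,
  ifelse(level < 500, 12L,
  ifelse(level < 1000, 13L,
  ifelse(level < 5000, 14L,
  ifelse(level < 10000, 15L, 16L)))))))
}

duplication_levels <- function(stats, limits) {
  tab <- dup_table(stats$dup)
  total <- stats$dup$total_reads
  cal <- stats$dup$count_at_limit
  ded <- rep(0, 16L)
  raw <- rep(0, 16L)
  ded_total <- raw_total <- 0
  if (nrow(tab) > 0L) {
    lv <- table(tab$count)
    for (j in seq_along(lv)) {
      level <- as.integer(names(lv)[j])
      m <- as.numeric(lv[j])
      m_corr <- m * corrected_count(level, cal, total) / level
      slot <- dup_slot(level)
      ded[slot] <- ded[slot] + m_corr
      raw[slot] <- raw[slot] + m_corr * level
      ded_total <- ded_total + m_corr
      raw_total <- raw_total + m_corr * level
    }
  }
  pct_ded <- if (ded_total > 0) 100 * ded / ded_total else rep(0, 16L)
  pct_raw <- if (raw_total > 0) 100 * raw / raw_total else rep(0, 16L)
  dedup_pct <- if (raw_total > 0) 100 * ded_total / raw_total else 100
  rows <- data.frame(`Duplication Level` = DUP_LABELS,
                     `Percentage of deduplicated` = pct_ded,
                     `Percentage of total` = pct_raw,
                     check.names = FALSE, stringsAsFactors = FALSE)
  g <- grade(dedup_pct, limit_value(limits, "duplication", "warn"),
             limit_value(limits, "duplication", "error"), "low")
  new_module("duplication", g, names(rows), rows,
             extra = list(total_deduplicated_percentage = dedup_pct))
}

revcomp <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

# longest aligned stretch with at most one mismatch, over all offsets
best_overlap_1mm <- function(a, b) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  na <- length(av)
  nb <- length(bv)
  best <- 0L
  best_mm <- 0L
  for (off in (-(nb - 1L)):(na - 1L)) {
    ia <- max(1L, 1L + off):min(na, nb + off)
    if (length(ia) <= best) next
    m <- av[ia] == bv[ia - off]
    n <- length(m)
    mm <- which(!m)
    if (length(mm) == 0L) {
      if (n > best) { best <- n; best_mm <- 0L }
      next
    }
    bounds <- c(0L, mm, n + 1L)
    runs0 <- diff(bounds) - 1L
    r0 <- max(runs0)
    if (r0 > best) { best <- r0; best_mm <- 0L }
    if (length(bounds) >= 3L) {
      runs1 <- bounds[-(1:2)] - bounds[seq_len(length(bounds) - 2L)] - 1L
      r1 <- max(runs1)
      if (r1 > best) { best <- r1; best_mm <- 1L }
    }
  }
  list(len = best, mm = best_mm)
}

contaminant_source <- function(seq, contaminants, min_overlap = 20L) {
  best_len <- min_overlap - 1L
  label <- "No Hit"
  for (i in seq_len(nrow(contaminants))) {
    for (cs in c(contaminants$sequence[i], revcomp(contaminants$sequence[i]))) {
      hit <- best_overlap_1mm(seq, cs)
      if (hit$len > best_len) {
        best_len <- hit$len
        idpct <- round(100 * (hit$len - hit$mm) / hit$len)
        label <- sprintf("%s (%d%% over %dbp)", contaminants$name[i],
                         idpct, hit$len)
      }
    }
  }
  label
}

overrepresented_sequences <- function(stats, limits, contaminants) {
  tab <- dup_table(stats$dup)
  total <- stats$n_reads
  warn_t <- limit_value(limits, "overrepresented", "warn", 0.1)
  err_t <- limit_value(limits, "overrepresented", "error", 1)
  pct <- 100 * tab$count / total
  keep <- which(pct > warn_t & nchar(tab$sequence) > 0L)
  keep <- keep[order(-tab$count[keep])]
  rows <- data.frame(
    Sequence = tab$sequence[keep],
    Count = tab$count[keep],
    Percentage = pct[keep],
    `Possible Source` = vapply(tab$sequence[keep], contaminant_source,
                               "", contaminants = contaminants,
                               USE.NAMES = FALSE),
    check.names = FALSE, stringsAsFactors = FALSE)
  g <- if (any(pct[keep] > err_t)) "fail"
       else if (length(keep)) "warn" else "pass"
  new_module("overrepresented", g, names(rows), rows)
}

adapter_content <- function(stats, limits, groups) {
  L <- stats$max_len
  eff <- L - ADAPTER_MIN_SEED + 1L
  nad <- nrow(stats$adapters)
  if (eff < 1L || nad == 0L) {
    rows <- as.data.frame(
      matrix(nrow = 0L, ncol = 1L + nad,
             dimnames = list(NULL, c("Position", stats$adapters$name))))
    return(new_module("adapter", "pass", names(rows), rows))
  }
  n_ge <- rev(cumsum(rev(stats$len_hist[-1L])))       # reads of length >= p
  cum <- t(apply(stats$adapter_first[, seq_len(L), drop = FALSE], 1L, cumsum))
  if (nad == 1L) cum <- matrix(cum, nrow = 1L)
  pct <- sweep(cum, 2L, pmax(n_ge, 1), "/") * 100
  pct[, n_ge == 0] <- 0
  gkeep <- which(groups$start <= eff)
  vals <- matrix(0, nrow = length(gkeep), ncol = nad)
  for (gi in seq_along(gkeep)) {
    cols <- seq.int(groups$start[gkeep[gi]],
                    min(groups$end[gkeep[gi]], eff))
    vals[gi, ] <- rowMeans(pct[, cols, drop = FALSE])
  }
  rows <- data.frame(Position = groups$label[gkeep], vals,
                     check.names = FALSE, stringsAsFactors = FALSE)
  names(rows) <- c("Position", stats$adapters$name)
  g <- grade(max(pct[, seq_len(eff)]),
             limit_value(limits, "adapter", "warn"),
             limit_value(limits, "adapter", "error"), "high")
  new_module("adapter", g, names(rows), rows)
}

kmer_content <- function(stats, limits) {
  if (is.null(stats$kmer_counts) || ncol(stats$kmer_counts) == 0L) {
    rows <- data.frame(Sequence = character(0), Count = numeric(0),
                       PValue = numeric(0), `Obs/Exp Max` = numeric(0),
                       `Max Obs/Exp Position` = character(0),
                       check.names = FALSE, stringsAsFactors = FALSE)
    return(new_module("kmer", "pass", names(rows), rows))
  }
  km <- stats$kmer_counts
  tk <- rowSums(km)
  np <- colSums(km)
  N <- sum(np)
  cand <- which(tk >= 2L)
  # Bonferroni over every k-mer x position cell actually tested, so a
  # uniform-random library is not flagged by sheer number of cells
  n_tests <- max(1, length(cand) * ncol(km))
  best_p <- numeric(0)
  out <- list()
  for (kidx in cand) {
    prob <- tk[kidx] / N
    obs <- km[kidx, ]
    exp <- prob * np
    ratio <- ifelse(exp > 0, obs / exp, 0)
    pv <- stats::pbinom(obs - 1, np, prob, lower.tail = FALSE)
    pv[obs == 0] <- 1
    pv <- pmin(1, pv * n_tests)
    j <- which.min(pv)
    if (pv[j] < 0.01) {
      out[[length(out) + 1L]] <- data.frame(
        Sequence = kmer_string(kidx - 1L, stats$kmer_k),
        Count = tk[kidx], PValue = pv[j],
        `Obs/Exp Max` = ratio[j],
        `Max Obs/Exp Position` = as.character(j),
        check.names = FALSE, stringsAsFactors = FALSE)
      best_p <- c(best_p, pv[j])
    }
  }
  if (length(out)) {
    rows <- do.call(rbind, out)
    ord <- order(rows$PValue, -rows$Count)
    rows <- rows[ord[seq_len(min(20L, nrow(rows)))], , drop = FALSE]
    score <- -log10(max(min(best_p), 1e-300))
  } else {
    rows <- data.frame(Sequence = character(0), Count = numeric(0),
                       PValue = numeric(0), `Obs/Exp Max` = numeric(0),
                       `Max Obs/Exp Position` = character(0),
                       check.names = FALSE, stringsAsFactors = FALSE)
    score <- 0
  }
  g <- grade(score, limit_value(limits, "kmer", "warn", 2),
             limit_value(limits, "kmer", "error", 5), "high")
  new_module("kmer", g, names(rows), rows)
}

kmer_string <- function(code, k) {
  letters4 <- c("A", "C", "G", "T")
  out <- character(k)
  for (i in k:1) {
    out[i] <- letters4[code %% 4L + 1L]
    code <- code %/% 4L
  }
  paste(out, collapse = "")
}

## ---- report assembly --------------------------------------------------

#' Build a graded QC report from collected statistics
#'
#' Runs every analysis module on the accumulator, grading each against
#' the limits. Modules disabled in the limits (`ignore 1`) are omitted,
#' as is the per-tile module when no tile ids could be parsed and every
#' read-data module when the input held no reads.
#'
#' @param stats A `qc_stats` accumulator from [qc_collect()].
#' @param limits Grading thresholds from [load_limits()].
#' @param contaminants Contaminant list from [load_contaminants()].
#' @param nogroup Disable base-position binning (single-base columns).
#' @return A `qc_report`: ordered list of graded module results.
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(rep(c("@r", "ACGT", "+", "IIII"), 3), fq)
#' rep <- qc_report(qc_collect(fq))
#' summary(rep)
#' @export
qc_report <- function(stats, limits = load_limits(),
                      contaminants = load_contaminants(),
                      nogroup = FALSE) {
  if (is.null(stats$encoding)) {
    stats$encoding <- detect_encoding(
      if (is.finite(stats$min_qchar)) stats$min_qchar else 33L)
  }
  mods <- list()
  add <- function(key, m) {
    if (!is.null(m) && !module_ignored(limits, MODULE_LIMIT_KEYS[key])) {
      mods[[unname(MODULE_TITLES[key])]] <<- m
    }
  }
  mods[[MODULE_TITLES[["basic"]]]] <- basic_statistics(stats)
  if (stats$n_reads > 0L) {
    has_pos <- stats$max_len > 0L
    if (has_pos) {
      groups <- make_base_groups(stats$max_len, nogroup = nogroup)
      add("per_base_quality", per_base_quality(stats, limits, groups))
      add("per_tile", per_tile_quality(stats, limits, groups))
      add("per_seq_quality", per_sequence_quality(stats, limits))
      add("per_base_content", per_base_content(stats, limits, groups))
      add("per_seq_gc", per_sequence_gc(stats, limits))
      add("per_base_n", per_base_n(stats, limits, groups))
    }
    add("length_dist", length_distribution(stats, limits))
    add("duplication", duplication_levels(stats, limits))
    add("overrepresented",
        overrepresented_sequences(stats, limits, contaminants))
    if (has_pos) {
      add("adapter", adapter_content(stats, limits, groups))
      if (stats$kmer_on) add("kmer", kmer_content(stats, limits))
    }
  }
  structure(list(filename = stats$filename, version = "0.11.8",
                 modules = mods),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$filename, "\n", sep = "")
  for (m in x$modules) {
    cat(sprintf("  %-4s %s\n", toupper(m$grade), m$name))
  }
  invisible(x)
}

#' @export
summary.qc_report <- function(object, ...) {
  data.frame(
    module = vapply(object$modules, `[[`, "", "name"),
    grade = vapply(object$modules, `[[`, "", "grade"),
    row.names = NULL, stringsAsFactors = FALSE)
}
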
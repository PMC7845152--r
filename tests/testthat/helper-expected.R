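# Independent grade evaluator: recomputes every module statistic
# definitionally from the raw FASTQ (whole file in memory, per-position
# loops, no use of the package's accumulator or module code) and applies
# the documented default threshold rules. Thresholds are restated here
# on purpose rather than loaded through the package.
#
# Positional statistics are evaluated per position (ungrouped); the
# fixtures graded with it keep quality and composition homogeneous
# enough that position binning cannot move a statistic across a
# threshold.

exp_rule_low <- function(v, warn, err) {
  if (v < err) "fail" else if (v < warn) "warn" else "pass"
}
exp_rule_high <- function(v, warn, err) {
  if (v > err) "fail" else if (v > warn) "warn" else "pass"
}
exp_worst <- function(...) {
  g <- c(...)
  if ("fail" %in% g) "fail" else if ("warn" %in% g) "warn" else "pass"
}
# lowest value whose cumulative count reaches p percent
exp_pctl <- function(v, p) sort(v)[ceiling(p * length(v) / 100)]

exp_tile_of <- function(name) {
  p <- strsplit(name, ":", fixed = TRUE)[[1L]]
  cand <- if (length(p) >= 7L) p[5L] else if (length(p) >= 5L) p[3L] else
    return(NA_integer_)
  suppressWarnings(as.integer(cand))
}

expected_report <- function(path, adapters = load_adapters()) {
  ln <- readLines(path, warn = FALSE)
  nms <- substring(ln[c(TRUE, FALSE, FALSE, FALSE)], 2L)
  bases <- toupper(ln[c(FALSE, TRUE, FALSE, FALSE)])
  quals <- ln[c(FALSE, FALSE, FALSE, TRUE)]
  n <- length(bases)
  lens <- nchar(bases)
  L <- max(lens)
  pos_i <- which(lens > 0L)

  bm <- matrix(NA_character_, nrow = n, ncol = L)
  qm <- matrix(NA_integer_, nrow = n, ncol = L)
  for (i in pos_i) {
    bm[i, seq_len(lens[i])] <- strsplit(bases[i], "", fixed = TRUE)[[1L]]
    qm[i, seq_len(lens[i])] <- utf8ToInt(quals[i])
  }
  offset <- if (min(qm, na.rm = TRUE) <= 63L) 33L else 64L
  q <- qm - offset

  grades <- c("Basic Statistics" = "pass")
  values <- list()

  # per base sequence quality
  med <- lq <- mean_q <- numeric(L)
  for (p in seq_len(L)) {
    v <- q[!is.na(q[, p]), p]
    med[p] <- exp_pctl(v, 50)
    lq[p] <- exp_pctl(v, 25)
    mean_q[p] <- mean(v)
  }
  grades["Per base sequence quality"] <-
    exp_worst(exp_rule_low(min(med), 25, 20),
              exp_rule_low(min(lq), 10, 5))
  values$per_base_median <- med
  values$per_base_mean <- mean_q

  # per tile sequence quality (present only when tile ids parse)
  tiles <- vapply(nms, exp_tile_of, integer(1L), USE.NAMES = FALSE)
  if (any(!is.na(tiles))) {
    worst <- 0
    for (tl in unique(tiles[!is.na(tiles)])) {
      sel <- which(tiles == tl & lens > 0L)
      for (p in seq_len(L)) {
        tv <- q[sel, p]; tv <- tv[!is.na(tv)]
        av <- q[!is.na(q[, p]) & !is.na(tiles), p]
        if (length(tv)) worst <- max(worst, mean(av) - mean(tv))
      }
    }
    grades["Per tile sequence quality"] <- exp_rule_high(worst, 5, 10)
  }

  # per sequence quality scores: mode of truncated mean quality
  mq <- floor(rowSums(q, na.rm = TRUE)[pos_i] / lens[pos_i])
  mq_tab <- table(mq)
  mode_q <- as.integer(names(mq_tab))[which.max(mq_tab)]
  grades["Per sequence quality scores"] <- exp_rule_low(mode_q, 27, 20)
  values$meanq_table <- mq_tab

  # per base sequence content
  dev <- 0
  content <- matrix(0, nrow = L, ncol = 4L,
                    dimnames = list(NULL, c("G", "A", "T", "C")))
  for (p in seq_len(L)) {
    col <- bm[, p]
    col <- col[!is.na(col) & col != "N"]
    if (length(col)) {
      pc <- 100 * c(sum(col == "G"), sum(col == "A"),
                    sum(col == "T"), sum(col == "C")) / length(col)
      content[p, ] <- pc
      dev <- max(dev, abs(pc[2] - pc[3]), abs(pc[1] - pc[4]))
    }
  }
  grades["Per base sequence content"] <- exp_rule_high(dev, 10, 20)
  values$content <- content

  # per sequence GC content: mode-centred normal, unit-bin integrals
  gcp <- floor(100 * rowSums(bm == "G" | bm == "C",
                             na.rm = TRUE)[pos_i] / lens[pos_i] + 0.5)
  h <- tabulate(gcp + 1L, 101L)
  tot <- sum(h)
  x <- 0:100
  peak <- which(h >= max(h) / 2)
  mode_gc <- sum(x[peak] * h[peak]) / sum(h[peak])
  sd_gc <- sqrt(sum(h * (x - mode_gc)^2) / tot)
  theo <- if (sd_gc < 1e-9) ifelse(x == mode_gc, tot, 0) else
    tot * (pnorm(x + 0.5, mode_gc, sd_gc) - pnorm(x - 0.5, mode_gc, sd_gc))
  gc_dev <- 100 * sum(abs(h - theo)) / tot
  grades["Per sequence GC content"] <- exp_rule_high(gc_dev, 15, 30)
  values$gc_hist <- h

  # per base N content
  n_pct <- numeric(L)
  for (p in seq_len(L)) {
    col <- bm[, p]; col <- col[!is.na(col)]
    n_pct[p] <- 100 * sum(col == "N") / length(col)
  }
  grades["Per base N content"] <- exp_rule_high(max(n_pct), 5, 20)
  values$n_pct <- n_pct

  # sequence length distribution
  grades["Sequence Length Distribution"] <-
    if (any(lens == 0L)) "fail" else
      if (min(lens) != max(lens)) "warn" else "pass"

  # duplication + overrepresentation (exact: n is below the tracker cap)
  keys <- substr(bases, 1L, 50L)
  tab <- table(keys)
  dedup <- 100 * length(tab) / n
  grades["Sequence Duplication Levels"] <- exp_rule_low(dedup, 70, 50)
  values$dedup_pct <- dedup
  pct <- 100 * as.numeric(tab) / n
  pct <- pct[names(tab) != ""]
  grades["Overrepresented sequences"] <-
    if (any(pct > 1)) "fail" else if (any(pct > 0.1)) "warn" else "pass"

  # adapter content: cumulative earliest-match percentage
  n_ge <- vapply(seq_len(L), function(p) sum(lens >= p), numeric(1))
  eff <- L - 12L + 1L
  worst_ad <- 0
  ad_max <- numeric(nrow(adapters))
  if (eff >= 1L) {
    for (j in seq_len(nrow(adapters))) {
      fp <- regexpr(adapters$sequence[j], bases, fixed = TRUE)
      hist <- tabulate(fp[fp > 0L], nbins = L)
      cumpct <- 100 * cumsum(hist) / pmax(n_ge, 1)
      ad_max[j] <- max(cumpct[seq_len(eff)])
      worst_ad <- max(worst_ad, ad_max[j])
    }
  }
  grades["Adapter Content"] <- exp_rule_high(worst_ad, 5, 10)
  values$adapter_max <- ad_max

  list(grades = grades, values = values, offset = offset)
}
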
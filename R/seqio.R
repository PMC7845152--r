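# Streaming readers for FASTQ (plain/gzip) and SAM, plus Phred encoding
# detection. Records are delivered strictly in file order; the parser
# buffers a bounded number of lines at a time so memory never depends on
# the number of reads in the file.

#' Open a stream of sequencing reads
#'
#' Resolves the input format (by explicit override, file extension and a
#' gzip magic-byte sniff) and returns a lightweight stream handle from
#' which records can be pulled with [next_record()] or, in bulk, with
#' [read_chunk()].
#'
#' Format resolution: `.bam` -> BAM, `.sam` -> SAM, `.gz` -> gzip FASTQ,
#' anything else -> plain FASTQ. Independently of the extension, a file
#' whose first two bytes are `1f 8b` is treated as gzip-compressed FASTQ.
#' BAM input requires the optional \pkg{Rsamtools} package.
#'
#' @param path Path to an existing FASTQ, gzip FASTQ, SAM or BAM file.
#' @param format Optional override, one of `"fastq"`, `"fastq.gz"`,
#'   `"sam"`, `"bam"`. Default `NULL` resolves from the file itself.
#' @return An object of class `qc_read_stream`.
#' @seealso [next_record()], [read_chunk()], [close_reads()]
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' s <- open_reads(fq)
#' next_record(s)
#' close_reads(s)
#' @export
open_reads <- function(path, format = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  fmt <- if (is.null(format)) {
    format_from_path(path)
  } else {
    match.arg(format, c("fastq", "fastq.gz", "sam", "bam"))
  }
  if (fmt %in% c("fastq", "fastq.gz") && is_gzip(path)) fmt <- "fastq.gz"

  stream <- new.env(parent = emptyenv())
  stream$path <- path
  stream$format <- fmt
  stream$line_no <- 0L
  stream$done <- FALSE
  if (fmt == "bam") {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("BAM input requires the 'Rsamtools' package; install it or ",
           "convert the file to SAM first (samtools view -h file.bam)",
           call. = FALSE)
    }
    stream$bam <- Rsamtools::BamFile(path, yieldSize = 10000L)
    Rsamtools::open.BamFile(stream$bam)
  } else {
    stream$con <- if (fmt == "fastq.gz") gzfile(path, "r") else file(path, "r")
  }
  class(stream) <- "qc_read_stream"
  stream
}

format_from_path <- function(path) {
  lower <- tolower(path)
  if (endsWith(lower, ".bam")) return("bam")
  if (endsWith(lower, ".sam")) return("sam")
  if (endsWith(lower, ".gz"))  return("fastq.gz")
  "fastq"
}

is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

#' Close a read stream
#'
#' @param stream A stream from [open_reads()].
#' @return `NULL`, invisibly.
#' @export
close_reads <- function(stream) {
  if (!stream$done) {
    if (stream$format == "bam") {
      Rsamtools::close.BamFile(stream$bam)
    } else {
      close(stream$con)
    }
    stream$done <- TRUE
  }
  invisible(NULL)
}

#' Pull the next batch of records from a stream
#'
#' Reads up to `n` records, returning a list with character vectors
#' `name`, `bases` (uppercased) and `quality`, or `NULL` at end of input.
#' FASTQ records are strict 4-line records; a final record with fewer
#' than 4 lines, a header not starting with `@`, a separator not
#' starting with `+`, or a base/quality length mismatch is a fatal error
#' reported with its line number. SAM header lines (leading `@`) and
#' alignment records whose SEQ field is `*` are skipped; a SAM QUAL of
#' `*` is replaced by all-`!` (Phred 0).
#'
#' @param stream A stream from [open_reads()].
#' @param n Maximum number of records to return.
#' @return A list (`name`, `bases`, `quality`) or `NULL` at end of input.
#' @export
read_chunk <- function(stream, n = 10000L) {
  switch(stream$format,
    fastq = , fastq.gz = fastq_chunk(stream, n),
    sam = sam_chunk(stream, n),
    bam = bam_chunk(stream, n),
    stop("unrecognized input format: ", stream$format, call. = FALSE)
  )
}

fastq_chunk <- function(stream, n) {
  lines <- readLines(stream$con, n = 4L * n, warn = FALSE)
  nl <- length(lines)
  if (nl == 0L) return(NULL)
  if (nl %% 4L != 0L) {
    stop("truncated FASTQ record at end of file (line ",
         stream$line_no + nl, ")", call. = FALSE)
  }
  heads <- lines[seq.int(1L, nl, 4L)]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad)) {
    stop("malformed FASTQ header at line ",
         stream$line_no + (bad[1L] - 1L) * 4L + 1L, call. = FALSE)
  }
  seps <- lines[seq.int(3L, nl, 4L)]
  bad <- which(!startsWith(seps, "+"))
  if (length(bad)) {
    stop("malformed FASTQ separator at line ",
         stream$line_no + (bad[1L] - 1L) * 4L + 3L, call. = FALSE)
  }
  bases <- toupper(lines[seq.int(2L, nl, 4L)])
  quals <- lines[seq.int(4L, nl, 4L)]
  bad <- which(nchar(bases) != nchar(quals))
  if (length(bad)) {
    stop("base/quality length mismatch at line ",
         stream$line_no + (bad[1L] - 1L) * 4L + 2L, call. = FALSE)
  }
  stream$line_no <- stream$line_no + nl
  list(name = substring(heads, 2L), bases = bases, quality = quals)
}

sam_chunk <- function(stream, n) {
  out_n <- out_b <- out_q <- character(0)
  repeat {
    lines <- readLines(stream$con, n = n, warn = FALSE)
    nl <- length(lines)
    if (nl == 0L) break
    first_line <- stream$line_no + 1L
    stream$line_no <- stream$line_no + nl
    keep <- !startsWith(lines, "@")
    if (!any(keep)) next
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    short <- lengths(fields) < 11L
    if (any(short)) {
      stop("malformed SAM record at line ",
           first_line + which(keep)[which(short)[1L]] - 1L, call. = FALSE)
    }
    nm <- vapply(fields, `[[`, "", 1L)
    sq <- vapply(fields, `[[`, "", 10L)
    ql <- vapply(fields, `[[`, "", 11L)
    use <- sq != "*"
    if (!any(use)) next
    nm <- nm[use]; sq <- toupper(sq[use]); ql <- ql[use]
    nostar <- ql == "*"
    if (any(nostar)) ql[nostar] <- strrep("!", nchar(sq[nostar]))
    if (any(nchar(sq) != nchar(ql))) {
      stop("SEQ/QUAL length mismatch in SAM record near line ",
           first_line, call. = FALSE)
    }
    out_n <- c(out_n, nm); out_b <- c(out_b, sq); out_q <- c(out_q, ql)
    if (length(out_n) >= n) break
  }
  if (length(out_n) == 0L) return(NULL)
  list(name = out_n, bases = out_b, quality = out_q)
}

bam_chunk <- function(stream, n) {
  param <- Rsamtools::ScanBamParam(what = c("qname", "seq", "qual"))
  res <- Rsamtools::scanBam(stream$bam, param = param)[[1L]]
  sq <- as.character(res$seq)
  if (length(sq) == 0L) return(NULL)
  ql <- as.character(res$qual)
  nm <- res$qname
  use <- !is.na(sq) & sq != "" & sq != "*"
  if (!any(use)) return(bam_chunk(stream, n))
  ql[is.na(ql) | ql == "*"] <- strrep("!", nchar(sq[is.na(ql) | ql == "*"]))
  list(name = nm[use], bases = toupper(sq[use]), quality = ql[use])
}

#' Pull a single read from a stream
#'
#' Convenience wrapper around [read_chunk()] with `n = 1`, honouring the
#' one-record-at-a-time streaming contract.
#'
#' @param stream A stream from [open_reads()].
#' @return A `fastq_record` (list with `name`, `bases`, `quality`) or
#'   `NULL` at end of input.
#' @export
next_record <- function(stream) {
  ch <- read_chunk(stream, n = 1L)
  if (is.null(ch)) return(NULL)
  structure(list(name = ch$name[1L], bases = ch$bases[1L],
                 quality = ch$quality[1L]),
            class = "fastq_record")
}

#' @export
print.fastq_record <- function(x, ...) {
  cat("<fastq_record> @", x$name, "\n  ", x$bases, "\n  ", x$quality, "\n",
      sep = "")
  invisible(x)
}

#' Detect the Phred quality encoding from the lowest quality character
#'
#' Mirrors the conventional boundary used by quality-control tools: any
#' file whose lowest quality character is below ASCII 64 is taken as
#' offset-33 ("Sanger / Illumina 1.9"); files whose lowest character is
#' 64 or above are taken as the legacy offset-64 encoding. Characters
#' below ASCII 33 are not valid Phred characters.
#'
#' @param min_quality_char_code Smallest ASCII code observed across all
#'   quality strings in the file.
#' @return A `phred_encoding`: list with `label` and `offset` (33 or 64).
#' @examples
#' detect_encoding(utf8ToInt("!"))  # offset 33
#' detect_encoding(utf8ToInt("B"))  # offset 64
#' @export
detect_encoding <- function(min_quality_char_code) {
  code <- as.integer(min_quality_char_code)
  if (is.na(code) || code < 33L) {
    stop("invalid quality character (ASCII code ", code,
         " is below the printable Phred range)", call. = FALSE)
  }
  enc <- if (code <= 63L) {
    list(label = "Sanger / Illumina 1.9", offset = 33L)
  } else {
    list(label = "Illumina <1.9", offset = 64L)
  }
  structure(enc, class = "phred_encoding")
}

#' @export
print.phred_encoding <- function(x, ...) {
  cat("<phred_encoding> ", x$label, " (offset ", x$offset, ")\n", sep = "")
  invisible(x)
}
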
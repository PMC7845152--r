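# Shared test helpers: tiny FASTQ/SAM writers and an independent
# MultiQC-style parser for the fastqc_data.txt dialect (written from
# the dialect definition, deliberately separate from the package's own
# read_qc_data()).

write_fastq <- function(bases, quality, name = NULL,
                        path = tempfile(fileext = ".fq")) {
  if (is.null(name)) name <- paste0("r", seq_along(bases))
  writeLines(as.vector(rbind(paste0("@", name), bases, "+", quality)),
             path)
  path
}

# constant-quality FASTQ from base strings
write_fastq_q <- function(bases, q = 30, name = NULL, ...) {
  quality <- vapply(nchar(bases),
                    function(l) strrep(intToUtf8(q + 33L), l), "")
  write_fastq(bases, quality, name = name, ...)
}

# stats accumulated directly from in-memory reads
stats_from_reads <- function(bases, quality, name = NULL, ...) {
  st <- new_qc_stats(...)
  update_stats(st, bases, quality, name)
  st$encoding <- detect_encoding(
    if (is.finite(st$min_qchar)) st$min_qchar else 33L)
  st
}

# MultiQC-style block parser: split on END_MODULE markers, dispatch on
# the ##FastQC magic line, collect per-section status + table
parse_fastqc_like <- function(path) {
  raw <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^##FastQC", raw)) {
    stop("file does not start with the ##FastQC magic line")
  }
  out <- list()
  for (section in strsplit(raw, ">>END_MODULE", fixed = TRUE)[[1L]]) {
    ls <- strsplit(section, "\n", fixed = TRUE)[[1L]]
    hdr_i <- grep("^>>", ls)
    if (length(hdr_i) == 0L) next
    hd <- strsplit(sub("^>>", "", ls[hdr_i[1L]]), "\t", fixed = TRUE)[[1L]]
    if (length(hd) < 2L) stop("module line without a status: ", ls[hdr_i[1L]])
    body <- ls[-seq_len(hdr_i[1L])]
    cols <- NULL
    hash <- grep("^#", body, value = TRUE)
    if (length(hash)) {
      cols <- strsplit(sub("^#", "", hash[length(hash)]), "\t",
                       fixed = TRUE)[[1L]]
    }
    data_lines <- body[!grepl("^#", body) & body != ""]
    tab <- if (length(data_lines)) {
      do.call(rbind, strsplit(data_lines, "\t", fixed = TRUE))
    } else NULL
    out[[hd[1L]]] <- list(status = hd[2L], columns = cols, table = tab)
  }
  out
}

read_summary <- function(path) {
  tok <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  stats::setNames(vapply(tok, `[[`, "", 1L), vapply(tok, `[[`, "", 2L))
}
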
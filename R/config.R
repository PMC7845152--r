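# Configuration parsing: module grading thresholds ("limits"), the
# adapter list searched in every read, and the contaminant list used to
# annotate overrepresented sequences. All three use the plain-text
# dialects of FastQC-compatible tools so existing user files drop in.

# module keys the limits dialect knows about; anything else is warned on
KNOWN_LIMIT_KEYS <- c(
  "duplication", "kmer", "n_content", "overrepresented",
  "quality_base_lower", "quality_base_median", "quality_base",
  "sequence", "gc_sequence", "quality_sequence", "tile",
  "sequence_length", "adapter"
)

qc_default_file <- function(name) {
  system.file("extdata", name, package = "readqc", mustWork = TRUE)
}

#' Load module grading thresholds (a "limits" file)
#'
#' The limits dialect is one whitespace-separated triple per line,
#' `key field value`, where `field` is `warn`, `error` or `ignore` and
#' `value` is numeric (`ignore` must be 0 or 1). `#` comments and blank
#' lines are skipped; unknown keys are kept but trigger a warning.
#' Without a path the packaged defaults are returned.
#'
#' @param path Optional path to a limits file; `NULL` loads the
#'   packaged defaults.
#' @return A `qc_limits` object: named list of named numeric vectors,
#'   e.g. `limits$duplication[["warn"]]`.
#' @examples
#' lim <- load_limits()
#' lim$duplication
#' @export
load_limits <- function(path = NULL) {
  if (is.null(path)) path <- qc_default_file("limits.txt")
  if (!file.exists(path)) stop("limits file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  limits <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    tok <- strsplit(line, "[ \t]+")[[1]]
    if (length(tok) != 3L) {
      stop("malformed limits line ", i, " (expected 'key field value'): ",
           lines[i], call. = FALSE)
    }
    key <- tok[1L]
    field <- tok[2L]
    val <- suppressWarnings(as.numeric(tok[3L]))
    if (!field %in% c("warn", "error", "ignore")) {
      stop("malformed limits line ", i, " (field must be warn/error/ignore)",
           call. = FALSE)
    }
    if (is.na(val)) {
      stop("malformed limits line ", i, " (non-numeric value): ", tok[3L],
           call. = FALSE)
    }
    if (field == "ignore" && !val %in% c(0, 1)) {
      stop("malformed limits line ", i, " (ignore must be 0 or 1)",
           call. = FALSE)
    }
    if (!key %in% KNOWN_LIMIT_KEYS) {
      warning("ignoring unknown limits key '", key, "' (line ", i, ")",
              call. = FALSE)
    }
    limits[[key]][[field]] <- val
  }
  structure(limits, class = "qc_limits")
}

limit_value <- function(limits, key, field, default = NA_real_) {
  v <- limits[[key]][[field]]
  if (is.null(v)) default else v
}

module_ignored <- function(limits, key) {
  isTRUE(limit_value(limits, key, "ignore", 0) == 1)
}

#' @export
print.qc_limits <- function(x, ...) {
  cat("<qc_limits> thresholds for", length(x), "module keys\n")
  for (k in names(x)) {
    cat(sprintf("  %-22s %s\n", k,
                paste(names(x[[k]]), unlist(x[[k]]), sep = "=",
                      collapse = "  ")))
  }
  invisible(x)
}

parse_sequence_list <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  nm <- sq <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (trimws(line) == "" || startsWith(trimws(line), "#")) next
    tok <- strsplit(line, "\t", fixed = TRUE)[[1]]
    tok <- tok[tok != ""]
    if (length(tok) < 2L) {
      stop("malformed ", what, " line ", i,
           " (expected name<TAB>sequence): ", line, call. = FALSE)
    }
    seqs <- toupper(trimws(tok[length(tok)]))
    if (!grepl("^[ACGT]+$", seqs)) {
      stop(what, " line ", i, ": sequence contains characters outside ",
           "{A,C,G,T}: ", seqs, call. = FALSE)
    }
    nm <- c(nm, trimws(paste(tok[-length(tok)], collapse = " ")))
    sq <- c(sq, seqs)
  }
  data.frame(name = nm, sequence = sq, stringsAsFactors = FALSE)
}

#' Load the adapter list
#'
#' Tab-separated `name<TAB>sequence` lines (names may contain spaces),
#' `#` comments skipped, order preserved. Without a path the packaged
#' default adapters are returned.
#'
#' @param path Optional path to an adapter list file.
#' @return A data frame with columns `name` and `sequence`.
#' @export
load_adapters <- function(path = NULL) {
  if (is.null(path)) path <- qc_default_file("adapter_list.txt")
  if (!file.exists(path)) stop("adapter file not found: ", path, call. = FALSE)
  out <- parse_sequence_list(path, "adapter list")
  if (anyDuplicated(out$name)) {
    stop("adapter list contains duplicate names", call. = FALSE)
  }
  out
}

#' Load the contaminant list
#'
#' Same dialect as [load_adapters()]. The packaged default is a curated
#' subset of widely published Illumina adapter and primer sequences.
#'
#' @param path Optional path to a contaminant list file.
#' @return A data frame with columns `name` and `sequence`.
#' @export
load_contaminants <- function(path = NULL) {
  if (is.null(path)) path <- qc_default_file("contaminant_list.txt")
  if (!file.exists(path)) {
    stop("contaminant file not found: ", path, call. = FALSE)
  }
  parse_sequence_list(path, "contaminant list")
}
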
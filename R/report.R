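# Report writers. Three outputs per input file: fastqc_data.txt (the
# block-structured text dialect existing aggregators parse), summary.txt
# (one PASS/WARN/FAIL line per module) and fastqc_report.html (an
# interactive page; plots rendered client-side from embedded data).
# Text outputs carry no timestamps, so reruns are byte-identical.

# up to 10 significant digits, trailing zeros trimmed
fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  has_dot <- grepl(".", out, fixed = TRUE) & !grepl("e", out, fixed = TRUE)
  out[has_dot] <- sub("\\.?0+$", "", out[has_dot])
  out
}

fmt_cell <- function(col) {
  if (is.numeric(col)) fmt_num(col) else as.character(col)
}

module_block <- function(m) {
  lines <- paste0(">>", m$name, "\t", m$grade)
  if (m$key == "duplication") {
    lines <- c(lines, paste0("#Total Deduplicated Percentage\t",
               fmt_num(m$extra$total_deduplicated_percentage)))
  }
  if (m$key != "basic") {
    lines <- c(lines, paste0("#", paste(m$header, collapse = "\t")))
  } else {
    lines <- c(lines, "#Measure\tValue")
  }
  if (nrow(m$rows) > 0L) {
    cells <- vapply(m$rows, fmt_cell, character(nrow(m$rows)))
    if (nrow(m$rows) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- c(lines, do.call(paste, c(as.data.frame(cells,
                                                     stringsAsFactors = FALSE),
                                       sep = "\t")))
  }
  c(lines, ">>END_MODULE")
}

#' Write the complete numeric report (fastqc_data.txt dialect)
#'
#' Emits the block-structured text dialect: a `##FastQC` version marker
#' first (downstream parsers dispatch on it), then one
#' `>>Title<TAB>grade` block per module with a `#`-prefixed header row
#' and tab-separated data rows, each terminated by `>>END_MODULE`. LF
#' line endings throughout.
#'
#' @param report A `qc_report` from [qc_report()].
#' @param path Output file; `NULL` returns the text invisibly instead.
#' @return The report text as a character vector of lines, invisibly.
#' @export
write_qc_data <- function(report, path = NULL) {
  lines <- c(paste0("##FastQC\t", report$version),
             unlist(lapply(report$modules, module_block), use.names = FALSE))
  if (!is.null(path)) writeLines(lines, path, sep = "\n")
  invisible(lines)
}

#' Write the one-line-per-module grade summary (summary.txt dialect)
#'
#' @param report A `qc_report` from [qc_report()].
#' @param path Output file; `NULL` returns the text invisibly instead.
#' @return The summary lines, invisibly.
#' @export
write_qc_summary <- function(report, path = NULL) {
  lines <- vapply(report$modules, function(m) {
    paste(toupper(m$grade), m$name, report$filename, sep = "\t")
  }, "", USE.NAMES = FALSE)
  if (!is.null(path)) writeLines(lines, path, sep = "\n")
  invisible(lines)
}

#' Parse a fastqc_data.txt dialect file
#'
#' Reads the block-structured report dialect back into module grades
#' and tables, converting numeric columns where possible. Used for
#' report round-trips and by [compare_reports()].
#'
#' @param path Path to a report file, or a character vector of lines.
#' @return A list with `version` and `modules` (each module a list with
#'   `grade`, `header`, `rows` and `extra`).
#' @export
read_qc_data <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else as.character(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "##FastQC")) {
    stop("not a fastqc_data.txt dialect file (missing ##FastQC marker)",
         call. = FALSE)
  }
  version <- sub("^##FastQC\t?", "", lines[1L])
  modules <- list()
  i <- 2L
  while (i <= length(lines)) {
    line <- lines[i]
    if (!startsWith(line, ">>")) { i <- i + 1L; next }
    head <- strsplit(sub("^>>", "", line), "\t", fixed = TRUE)[[1L]]
    title <- head[1L]
    grade <- if (length(head) > 1L) head[2L] else NA_character_
    i <- i + 1L
    header <- NULL
    extra <- list()
    body <- character(0)
    while (i <= length(lines) && lines[i] != ">>END_MODULE") {
      if (startsWith(lines[i], "#")) {
        tok <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1L]]
        if (length(tok) == 2L &&
            !is.na(suppressWarnings(as.numeric(tok[2L]))) &&
            is.null(header)) {
          extra[[tok[1L]]] <- as.numeric(tok[2L])
        } else {
          header <- tok
        }
      } else {
        body <- c(body, lines[i])
      }
      i <- i + 1L
    }
    i <- i + 1L   # skip END_MODULE
    rows <- if (length(body)) {
      sp <- strsplit(body, "\t", fixed = TRUE)
      ncol <- max(lengths(sp))
      df <- as.data.frame(
        do.call(rbind, lapply(sp, function(x) { length(x) <- ncol; x })),
        stringsAsFactors = FALSE)
      if (!is.null(header) && length(header) == ncol) names(df) <- header
      for (j in seq_along(df)) {
        num <- suppressWarnings(as.numeric(df[[j]]))
        if (!anyNA(num)) df[[j]] <- num
      }
      df
    } else {
      df <- as.data.frame(matrix(nrow = 0L,
                                 ncol = max(1L, length(header))))
      if (!is.null(header)) names(df) <- header
      df
    }
    modules[[title]] <- list(grade = grade, header = header, rows = rows,
                             extra = extra)
  }
  list(version = version, modules = modules)
}

#' Compare two reports cell by cell
#'
#' Parses two fastqc_data.txt dialect files and lists grade mismatches
#' and numeric cells differing beyond a relative tolerance. An empty
#' data frame means the reports agree.
#'
#' @param a,b Paths to (or line vectors of) report files.
#' @param tol Relative tolerance for numeric cells.
#' @return Data frame with columns `module`, `kind`, `detail`.
#' @export
compare_reports <- function(a, b, tol = 1e-2) {
  ra <- read_qc_data(a)
  rb <- read_qc_data(b)
  diffs <- list()
  note <- function(module, kind, detail) {
    diffs[[length(diffs) + 1L]] <<- data.frame(
      module = module, kind = kind, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (nm in union(names(ra$modules), names(rb$modules))) {
    ma <- ra$modules[[nm]]
    mb <- rb$modules[[nm]]
    if (is.null(ma) || is.null(mb)) {
      note(nm, "presence", "module missing from one report")
      next
    }
    if (!identical(ma$grade, mb$grade)) {
      note(nm, "grade", paste(ma$grade, "vs", mb$grade))
    }
    if (nrow(ma$rows) != nrow(mb$rows) || ncol(ma$rows) != ncol(mb$rows)) {
      note(nm, "shape", sprintf("%dx%d vs %dx%d", nrow(ma$rows),
                                ncol(ma$rows), nrow(mb$rows),
                                ncol(mb$rows)))
      next
    }
    for (j in seq_len(ncol(ma$rows))) {
      x <- ma$rows[[j]]
      y <- mb$rows[[j]]
      if (is.numeric(x) && is.numeric(y)) {
        rel <- abs(x - y) / pmax(abs(x), abs(y), 1e-10)
        bad <- which(rel > tol)
        for (r in bad) {
          note(nm, "numeric",
               sprintf("col %d row %d: %g vs %g", j, r, x[r], y[r]))
        }
      } else if (!identical(as.character(x), as.character(y))) {
        note(nm, "text", sprintf("col %d differs", j))
      }
    }
  }
  if (length(diffs)) do.call(rbind, diffs) else
    data.frame(module = character(0), kind = character(0),
               detail = character(0), stringsAsFactors = FALSE)
}

## ---- HTML report ------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# plot payload (plotly trace list) for one module, or NULL for none
module_plot <- function(m) {
  rows <- m$rows
  if (nrow(rows) == 0L) return(NULL)
  switch(m$key,
    per_base_quality = list(
      kind = "lines", xtitle = "Position in read (bp)",
      ytitle = "Phred quality",
      x = rows$Base,
      series = lapply(names(rows)[-1L], function(cn)
        list(name = cn, y = rows[[cn]]))),
    per_tile = {
      tiles <- sort(unique(rows$Tile))
      bases <- unique(rows$Base)
      z <- matrix(NA_real_, nrow = length(tiles), ncol = length(bases))
      z[cbind(match(rows$Tile, tiles), match(rows$Base, bases))] <- rows$Mean
      list(kind = "heatmap", xtitle = "Position in read (bp)",
           ytitle = "Tile", x = bases, y = as.character(tiles), z = z)
    },
    per_seq_quality = list(
      kind = "lines", xtitle = "Mean sequence quality",
      ytitle = "Number of reads", x = rows$Quality,
      series = list(list(name = "Reads", y = rows$Count))),
    per_base_content = list(
      kind = "lines", xtitle = "Position in read (bp)",
      ytitle = "Percent of calls", x = rows$Base,
      series = lapply(c("G", "A", "T", "C"), function(b)
        list(name = paste0("%", b), y = rows[[b]]))),
    per_seq_gc = list(
      kind = "lines", xtitle = "Mean GC content (%)",
      ytitle = "Number of reads", x = rows$`GC Content`,
      series = c(list(list(name = "GC count per read", y = rows$Count)),
                 if (!is.null(m$extra$theoretical))
                   list(list(name = "Theoretical distribution",
                             y = m$extra$theoretical)))),
    per_base_n = list(
      kind = "lines", xtitle = "Position in read (bp)",
      ytitle = "Percent N", x = rows$Base,
      series = list(list(name = "%N", y = rows$`N-Count`))),
    length_dist = list(
      kind = "lines", xtitle = "Sequence length (bp)",
      ytitle = "Number of reads", x = rows$Length,
      series = list(list(name = "Reads", y = rows$Count))),
    duplication = list(
      kind = "bars", xtitle = "Duplication level",
      ytitle = "Percent of library", x = rows$`Duplication Level`,
      series = list(
        list(name = "% of deduplicated",
             y = rows$`Percentage of deduplicated`),
        list(name = "% of total", y = rows$`Percentage of total`))),
    adapter = list(
      kind = "lines", xtitle = "Position in read (bp)",
      ytitle = "Percent of reads with adapter", x = rows$Position,
      series = lapply(names(rows)[-1L], function(cn)
        list(name = cn, y = rows[[cn]]))),
    NULL)
}

module_table_html <- function(m) {
  rows <- m$rows
  if (nrow(rows) == 0L) return("<p>No entries.</p>")
  if (nrow(rows) > 25L && m$key != "basic" && m$key != "overrepresented") {
    return("")   # large tables live in fastqc_data.txt
  }
  head <- paste0("<tr>", paste0("<th>", html_escape(names(rows)),
                                "</th>", collapse = ""), "</tr>")
  body <- apply(rows, 1L, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(fmt_cell(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  paste0("<table>", head, paste(body, collapse = ""), "</table>")
}

PLOT_JS <- "
function qcPlot(div, p) {
  var traces = [];
  if (p.kind === 'heatmap') {
    traces.push({type: 'heatmap', x: p.x, y: p.y, z: p.z,
                 colorscale: 'RdBu'});
  } else {
    for (var i = 0; i < p.series.length; i++) {
      var s = p.series[i];
      traces.push({type: p.kind === 'bars' ? 'bar' : 'scatter',
                   mode: 'lines', name: s.name, x: p.x, y: s.y});
    }
  }
  Plotly.newPlot(div, traces,
    {xaxis: {title: p.xtitle, type: 'category'},
     yaxis: {title: p.ytitle}, margin: {t: 20}});
}
var qcData = document.getElementById('qc-data');
var payload = JSON.parse(qcData.textContent);
for (var id in payload) { qcPlot(id, payload[id]); }
"

#' Write the interactive HTML report
#'
#' One section per module with a grade badge; plot data are embedded as
#' JSON and rendered client-side with the Plotly JavaScript library.
#' By default the plot library is referenced from its CDN URL to keep
#' the report small; `plotly = "none"` writes a plot-free page that
#' needs no network at all, and `plotly = "/path/to/plotly.js"` inlines
#' a local copy.
#'
#' @param report A `qc_report` from [qc_report()].
#' @param path Output file; `NULL` returns the HTML text invisibly.
#' @param plotly `"cdn"`, `"none"`, or a path to a plotly.js file to
#'   embed.
#' @return The HTML as a single string, invisibly.
#' @export
write_qc_html <- function(report, path = NULL, plotly = "cdn") {
  badges <- vapply(report$modules, function(m) m$grade, "")
  ids <- paste0("M", seq_along(report$modules) - 1L)
  plots <- lapply(report$modules, module_plot)
  use_plots <- !identical(plotly, "none")
  payload <- list()
  if (use_plots) {
    for (k in seq_along(plots)) {
      if (!is.null(plots[[k]])) {
        payload[[paste0("plot-", ids[k])]] <- plots[[k]]
      }
    }
  }
  lib_tag <- if (!use_plots) "" else if (identical(plotly, "cdn")) {
    "<script src=\"https://cdn.plot.ly/plotly-2.27.0.min.js\"></script>"
  } else {
    paste0("<script>",
           paste(readLines(plotly, warn = FALSE), collapse = "\n"),
           "</script>")
  }
  nav <- paste0(
    "<li><a href=\"#", ids, "\"><span class=\"badge ", badges, "\">",
    toupper(badges), "</span> ",
    html_escape(vapply(report$modules, `[[`, "", "name")), "</a></li>",
    collapse = "")
  sections <- vapply(seq_along(report$modules), function(k) {
    m <- report$modules[[k]]
    plot_div <- if (use_plots && !is.null(plots[[k]])) {
      paste0("<div class=\"plot\" id=\"plot-", ids[k], "\"></div>")
    } else ""
    paste0("<div class=\"module\" id=\"", ids[k], "\">",
           "<h2><span class=\"badge ", m$grade, "\">",
           toupper(m$grade), "</span> ", html_escape(m$name), "</h2>",
           plot_div, module_table_html(m), "</div>")
  }, "")
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>QC report: ", html_escape(report$filename), "</title>\n",
    lib_tag, "\n<style>\n",
    "body{font-family:sans-serif;margin:0;padding:0 1em;}",
    "h1{background:#20242c;color:#fff;margin:0 -16px;padding:12px;}",
    ".badge{display:inline-block;min-width:3.2em;text-align:center;",
    "border-radius:3px;padding:1px 4px;color:#fff;font-size:0.8em;}",
    ".badge.pass{background:#2e7d32;}.badge.warn{background:#ef6c00;}",
    ".badge.fail{background:#c62828;}",
    "table{border-collapse:collapse;margin:0.5em 0;}",
    "td,th{border:1px solid #bbb;padding:2px 8px;font-size:0.85em;}",
    ".plot{max-width:900px;height:420px;}",
    "ul.nav{list-style:none;padding-left:0;}ul.nav li{margin:2px 0;}",
    "\n</style>\n</head>\n<body>\n",
    "<h1>QC report: ", html_escape(report$filename), "</h1>\n",
    "<ul class=\"nav\">", nav, "</ul>\n",
    paste(sections, collapse = "\n"), "\n",
    "<script type=\"application/json\" id=\"qc-data\">",
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 8,
                     na = "null"),
    "</script>\n",
    if (use_plots) paste0("<script>", PLOT_JS, "</script>\n") else "",
    "</body>\n</html>\n")
  if (!is.null(path)) writeLines(html, path, sep = "", useBytes = TRUE)
  invisible(html)
}
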
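#' Assemble a nucleus signal table
#'
#' The central input of the pipeline: one row per enumerated nucleus, one
#' integer column of hybridization signal counts per panel probe. Only
#' completely scored nuclei belong in the table — the enumeration contract
#' is that every probe was clearly visible in every retained nucleus.
#'
#' @param counts integer matrix or data.frame, one column per panel probe
#'   (matched and reordered by name when column names are present).
#' @param panel a [probe_panel()].
#' @param nucleus_id optional character ids; defaults to `"n<row>"`.
#' @return A data.frame with column `nucleus_id` followed by one integer
#'   column per probe, in panel order.
#' @export
nucleus_table <- function(counts, panel, nucleus_id = NULL) {
  counts <- as.data.frame(counts)
  if (!is.null(colnames(counts)) && all(panel$name %in% colnames(counts))) {
    counts <- counts[, panel$name, drop = FALSE]
  } else if (ncol(counts) == nrow(panel)) {
    colnames(counts) <- panel$name
  } else {
    stop(sprintf("counts has %d columns; panel has %d probes",
                 ncol(counts), nrow(panel)))
  }
  check_counts(counts, panel)
  if (is.null(nucleus_id)) nucleus_id <- paste0("n", seq_len(nrow(counts)))
  out <- cbind(data.frame(nucleus_id = as.character(nucleus_id),
                          stringsAsFactors = FALSE), counts)
  rownames(out) <- NULL
  out
}

check_counts <- function(counts, panel) {
  for (p in panel$name) {
    v <- counts[[p]]
    if (is.character(v) || !all(is.finite(v)))
      stop(sprintf("non-numeric count in column '%s'", p))
    bad <- which(v != round(v))
    if (length(bad))
      stop(sprintf("non-integer count in column '%s', row %d", p, bad[1]))
    neg <- which(v < 0)
    if (length(neg))
      stop(sprintf("negative count in column '%s', row %d", p, neg[1]))
    counts[[p]] <- as.integer(v)
  }
  invisible(counts)
}

#' Extract the counts matrix of a nucleus table, in panel order
#' @param records a nucleus table (see [nucleus_table()]).
#' @param panel a [probe_panel()].
#' @return integer matrix, nuclei x probes.
#' @export
count_matrix <- function(records, panel) {
  missing <- setdiff(panel$name, colnames(records))
  if (length(missing))
    stop(sprintf("missing probe column(s): %s", paste(missing, collapse = ", ")))
  m <- as.matrix(records[, panel$name, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Read a tab-separated nucleus signal table
#'
#' The file carries a header of probe names (any column order; an optional
#' `nucleus_id` column is honored) and one nucleus per row. Rows with
#' missing, non-integer or negative cells are rejected with the offending
#' row and column named: the enumeration protocol only records nuclei with
#' clearly visible signals for every probe, so the file contract assumes
#' complete rows.
#'
#' @param path TSV path.
#' @param panel a [probe_panel()].
#' @return A nucleus table data.frame, rows in file order.
#' @export
read_signal_table <- function(path, panel) {
  if (!file.exists(path)) stop(sprintf("signal table not found: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  missing <- setdiff(panel$name, colnames(raw))
  if (length(missing))
    stop(sprintf("signal table %s lacks probe column(s): %s", path,
                 paste(missing, collapse = ", ")))
  counts <- raw[, panel$name, drop = FALSE]
  for (p in panel$name) {
    v <- counts[[p]]
    blank <- which(is.na(v) | !nzchar(trimws(v)))
    if (length(blank))
      stop(sprintf("missing count in column '%s', row %d", p, blank[1]))
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num != round(num))
    if (length(bad))
      stop(sprintf("non-integer count '%s' in column '%s', row %d",
                   v[bad[1]], p, bad[1]))
    neg <- which(num < 0)
    if (length(neg))
      stop(sprintf("negative count in column '%s', row %d", p, neg[1]))
    counts[[p]] <- as.integer(num)
  }
  ids <- if ("nucleus_id" %in% colnames(raw)) raw$nucleus_id else NULL
  nucleus_table(counts, panel, nucleus_id = ids)
}

#' Write a nucleus signal table as TSV
#' @param records a nucleus table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Aggregate nuclei into signal patterns (clones)
#'
#' Nuclei sharing the exact same signal-count vector form one signal
#' pattern; the pattern carried by the most nuclei is the major clone.
#' Patterns are ordered by multiplicity descending, ties broken by
#' lexicographically smallest count vector, so the first row is always the
#' major clone and the ordering is deterministic.
#'
#' @param records a nucleus table.
#' @param panel a [probe_panel()].
#' @return A data.frame with columns `pattern` (hyphen-joined counts, e.g.
#'   `"2-1-3-2-1-2-2-2-2-2"`), `multiplicity`, `frequency`, plus one count
#'   column per probe.
#' @export
aggregate_patterns <- function(records, panel) {
  if (nrow(records) == 0L) stop("no nuclei to aggregate")
  m <- count_matrix(records, panel)
  key <- apply(m, 1L, paste, collapse = "-")
  tab <- table(key)
  uniq <- m[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  mult <- as.integer(tab[ukey])
  ord <- order(-mult, ukey_sortable(uniq))
  uniq <- uniq[ord, , drop = FALSE]
  mult <- mult[ord]
  out <- data.frame(pattern = apply(uniq, 1L, paste, collapse = "-"),
                    multiplicity = mult,
                    frequency = mult / nrow(records),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(uniq))
  rownames(out) <- NULL
  out
}

# lexicographic sort key over rows of an integer matrix (vector order,
# coordinate by coordinate)
ukey_sortable <- function(m) {
  width <- max(nchar(as.character(max(m))), 1L)
  apply(m, 1L, function(r) paste(formatC(r, width = width, flag = "0"),
                                 collapse = "-"))
}

#' Validate a sample against the minimum-enumeration contract
#'
#' Samples are expected to carry at least `min_nuclei` completely scored
#' nuclei. Falling short is a warning-level flag (the sample is still
#' analyzable); an empty sample is an error-level flag.
#'
#' @param records a nucleus table.
#' @param min_nuclei minimum nuclei per sample (default 250).
#' @return A list with `n_nuclei`, `min_nuclei`, `level` (`"pass"`,
#'   `"warning"`, `"error"`) and `message`.
#' @export
validate_sample <- function(records, min_nuclei = 250L) {
  n <- nrow(records)
  if (n == 0L) {
    level <- "error"
    msg <- "sample contains no nuclei"
  } else if (n < min_nuclei) {
    level <- "warning"
    msg <- sprintf("only %d nuclei enumerated (minimum %d)", n, min_nuclei)
  } else {
    level <- "pass"
    msg <- sprintf("%d nuclei enumerated", n)
  }
  list(n_nuclei = n, min_nuclei = as.integer(min_nuclei), level = level,
       message = msg)
}

#' Parse a hyphen-joined pattern string into an integer vector
#' @param pattern e.g. `"8-4-4-4-3-2-4-5"`.
#' @return integer vector.
#' @export
parse_pattern <- function(pattern) {
  as.integer(strsplit(pattern, "-", fixed = TRUE)[[1]])
}

#' Format an integer count vector in hyphen notation
#' @param counts integer vector.
#' @return character scalar like `"8-4-4-4-3-2-4-5"`.
#' @export
format_pattern <- function(counts) paste(counts, collapse = "-")
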
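# Readers and writers for the plain-text interchange formats: count tables
# with a #library_sizes header line, two-column TSVs (lengths, truth labels,
# term annotations), one-id-per-line gene sets and 12-column hit tables.

#' Write a count table as TSV
#'
#' Writes a `#library_sizes` comment line (`tissue=reads` pairs) followed by
#' a header row (`gene_id` plus one column per tissue) and one row per gene.
#'
#' @param x A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_sizes\t",
                    paste(sprintf("%s=%.0f", names(x$library_sizes),
                                  x$library_sizes), collapse = "\t")), con)
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from TSV
#'
#' Accepts the format written by [write_count_table()]. Library sizes come
#' from the `#library_sizes` header line when present, else from the
#' `library_sizes` argument (a named vector or the path of a two-column
#' `tissue`/`reads` TSV); as a last resort the column sums are used with a
#' message.
#'
#' @param path Path to the TSV.
#' @param library_sizes Optional named numeric vector or sidecar TSV path.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, library_sizes = NULL) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#library_sizes")) {
    parts <- strsplit(sub("^#library_sizes\t", "", first), "\t")[[1]]
    kv <- strsplit(parts, "=")
    library_sizes <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                              vapply(kv, `[`, "", 1))
  } else if (is.character(library_sizes) && length(library_sizes) == 1 &&
             file.exists(library_sizes)) {
    ls_df <- read.delim(library_sizes, header = TRUE)
    library_sizes <- setNames(as.numeric(ls_df[[2]]),
                              as.character(ls_df[[1]]))
  }
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (is.null(library_sizes)) {
    message("no library sizes supplied; using column sums")
    library_sizes <- colSums(m)
  }
  count_table(m, library_sizes)
}

#' Read gene lengths from a two-column TSV
#'
#' @param path TSV with columns `gene_id`, `length` (header optional but
#'   recommended).
#' @return Named numeric vector of lengths in bp.
#' @export
read_gene_lengths <- function(path) {
  df <- read.delim(path, header = TRUE)
  if (!is.numeric(df[[2]]))  # headerless file: first row was data
    df <- read.delim(path, header = FALSE)
  out <- setNames(as.numeric(df[[2]]), as.character(df[[1]]))
  if (any(!is.finite(out)) || any(out <= 0))
    stopf("%s: lengths must be positive", path)
  out
}

#' Read a term annotation from a two-column TSV
#'
#' @param path TSV with columns `gene_id`, `term_id`.
#' @param universe Optional background universe, see [term_annotation()].
#' @return A [term_annotation()].
#' @export
read_term_annotation <- function(path, universe = NULL) {
  df <- read.delim(path, header = TRUE)
  term_annotation(df, universe = universe)
}

#' Read a gene set (one identifier per line)
#'
#' @param path Text file with one gene id per line; a leading `gene_id`
#'   header line is skipped.
#' @return Character vector.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  if (length(x) && identical(tolower(x[1]), "gene_id")) x <- x[-1]
  unique(x)
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits Data frame with the standard outfmt-6 columns (see
#'   [read_hits()]).
#' @param path Output path. No header is written, matching the standard
#'   format.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  stopifnot(all(OUTFMT6_COLS %in% names(hits)))
  write.table(format(hits[, OUTFMT6_COLS], scientific = TRUE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
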
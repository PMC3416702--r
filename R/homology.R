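# Best-hit selection from tabular protein-alignment results and partition of
# a focal gene set by cross-species conservation.

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore")

#' Read a tabular alignment hit file (BLAST outfmt 6)
#'
#' Reads the standard 12-column tab-separated hit format. Lines starting with
#' `#` are skipped; malformed numeric fields are reported with their line
#' number.
#'
#' @param path Path to the hit table.
#' @return Data frame with the standard columns `qseqid`, `sseqid`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`.
#' @export
read_hits <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 12)
    stopf("%s: expected 12 tab-separated columns, found %d", path, ncol(df))
  df <- df[, 1:12]
  names(df) <- OUTFMT6_COLS
  for (col in c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(val))
      stopf("%s: malformed numeric field '%s' at line %d", path, col,
            which(is.na(val))[1])
    df[[col]] <- val
  }
  if (any(df$evalue < 0)) stopf("%s: negative E-value", path)
  if (any(df$pident < 0 | df$pident > 100))
    stopf("%s: percent identity outside [0, 100]", path)
  df
}

#' Select the best alignment hit per query
#'
#' Filters hits and keeps, for each query, the row with the lowest E-value;
#' ties are broken by higher bitscore, then by lexicographically smallest
#' subject identifier. Two boundary conventions are supported: homolog
#' screening uses an inclusive E-value cutoff (`evalue <= e_max`, default
#' 1e-10), while probe assignment uses a strict one (`e_strict = TRUE`, i.e.
#' `evalue < e_max`) together with a strict identity floor
#' (`pident > min_identity`).
#'
#' @param hits Data frame of hits as from [read_hits()] (columns `qseqid`,
#'   `sseqid`, `pident`, `evalue`, `bitscore` are required).
#' @param subject_filter Optional character vector; hits to subjects outside
#'   it are discarded before selection.
#' @param e_max E-value cutoff (default `1e-10`).
#' @param e_strict Use `evalue < e_max` instead of `<=` (default `FALSE`).
#' @param min_identity Optional strict percent-identity floor on the `pident`
#'   column (0-100 scale; a fractional identity cutoff of 0.8 corresponds to
#'   `min_identity = 80`).
#' @param subject_regex Optional regex stripped from subject identifiers
#'   (e.g. a transcript suffix such as `"\\.\\d+$"`); applied before
#'   `subject_filter`. Identifiers are never normalized implicitly.
#' @return Data frame with one row per retained query: `query_id`,
#'   `subject_id`, `pident`, `evalue`, `bitscore`.
#' @export
best_hits <- function(hits, subject_filter = NULL, e_max = 1e-10,
                      e_strict = FALSE, min_identity = NULL,
                      subject_regex = NULL) {
  need <- c("qseqid", "sseqid", "pident", "evalue", "bitscore")
  if (!all(need %in% names(hits)))
    stopf("'hits' must contain columns: %s", paste(need, collapse = ", "))
  if (!is.numeric(e_max) || e_max <= 0) stopf("'e_max' must be positive")
  if (!is.null(subject_regex))
    hits$sseqid <- sub(subject_regex, "", hits$sseqid)
  keep <- if (e_strict) hits$evalue < e_max else hits$evalue <= e_max
  if (!is.null(min_identity)) keep <- keep & hits$pident > min_identity
  if (!is.null(subject_filter)) keep <- keep & hits$sseqid %in% subject_filter
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(query_id = character(), subject_id = character(),
                      pident = numeric(), evalue = numeric(),
                      bitscore = numeric()))
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  data.frame(query_id = hits$qseqid, subject_id = hits$sseqid,
             pident = hits$pident, evalue = hits$evalue,
             bitscore = hits$bitscore, row.names = NULL)
}

#' Best hits in both directions
#'
#' Convenience wrapper applying [best_hits()] to a forward (focal-vs-other)
#' and a reverse (other-vs-focal) hit table with the same filters. The two
#' directions are reported separately, never merged.
#'
#' @param hits_forward,hits_reverse Hit tables as from [read_hits()].
#' @param ... Passed to [best_hits()].
#' @return List with elements `forward` and `reverse`.
#' @export
best_hits_both <- function(hits_forward, hits_reverse, ...) {
  list(forward = best_hits(hits_forward, ...),
       reverse = best_hits(hits_reverse, ...))
}

as_hit_map <- function(m) {
  if (is.data.frame(m)) {
    stopifnot(all(c("query_id", "subject_id") %in% names(m)))
    setNames(as.character(m$subject_id), as.character(m$query_id))
  } else if (is.character(m)) {
    if (length(m) && is.null(names(m))) stopf("hit map must be named")
    m
  } else stopf("hit map must be a best_hits() data frame or named vector")
}

#' Partition a focal gene set by cross-species conservation
#'
#' Splits the focal set into genes with a qualifying best hit in both other
#' species' datasets, in exactly one, or in neither (`distinct`). The
#' matched-subject sets (the image of each map over the focal genes) are
#' returned as well.
#'
#' @param focal Character vector of focal gene identifiers.
#' @param map_a,map_b Best-hit maps keyed by focal gene identifiers: either
#'   the data frame returned by [best_hits()] or a named character vector
#'   `query -> subject`.
#' @return A `homology_partition` object: list with `focal`, `hit_both`,
#'   `hit_a_only`, `hit_b_only`, `distinct`, `matched_a`, `matched_b`.
#' @export
conservation_partition <- function(focal, map_a, map_b) {
  focal <- unique(as.character(focal))
  a <- as_hit_map(map_a)
  b <- as_hit_map(map_b)
  in_a <- intersect(focal, names(a))
  in_b <- intersect(focal, names(b))
  hit_both <- intersect(in_a, in_b)
  hit_a_only <- setdiff(in_a, in_b)
  hit_b_only <- setdiff(in_b, in_a)
  distinct <- setdiff(focal, union(in_a, in_b))
  parts <- list(hit_both, hit_a_only, hit_b_only, distinct)
  stopifnot(sum(lengths(parts)) == length(focal),
            !anyDuplicated(unlist(parts)))
  structure(list(focal = focal, hit_both = hit_both,
                 hit_a_only = hit_a_only, hit_b_only = hit_b_only,
                 distinct = distinct,
                 matched_a = unique(unname(a[in_a])),
                 matched_b = unique(unname(b[in_b]))),
            class = "homology_partition")
}

#' Count and percentage summary of a conservation partition
#'
#' Reports each subset count with its percentage (two decimal places) of the
#' focal set, and the matched-subject counts as percentages of the other
#' species' dataset sizes when those are supplied.
#'
#' @param partition A [conservation_partition()] result.
#' @param size_a,size_b Optional sizes of the other species' gene datasets,
#'   the denominators for the matched-subject percentages. Must be positive
#'   when given.
#' @return Data frame with columns `subset`, `count`, `denominator`,
#'   `percent`.
#' @export
partition_summary <- function(partition, size_a = NULL, size_b = NULL) {
  stopifnot(inherits(partition, "homology_partition"))
  nf <- length(partition$focal)
  if (nf == 0) stopf("zero-size focal set")
  for (s in c(size_a, size_b))
    if (!is.null(s) && s <= 0) stopf("zero or negative dataset size")
  pct <- function(count, den) round(100 * count / den, 2)
  rows <- data.frame(
    subset = c("focal", "hit_a", "hit_b", "hit_both", "hit_a_only",
               "hit_b_only", "distinct"),
    count = c(nf,
              length(partition$hit_both) + length(partition$hit_a_only),
              length(partition$hit_both) + length(partition$hit_b_only),
              length(partition$hit_both), length(partition$hit_a_only),
              length(partition$hit_b_only), length(partition$distinct)),
    denominator = nf)
  subj <- data.frame(
    subset = c("subjects_a", "subjects_b"),
    count = c(length(partition$matched_a), length(partition$matched_b)),
    denominator = c(size_a %||% NA_real_, size_b %||% NA_real_))
  out <- rbind(rows, subj)
  out$percent <- pct(out$count, out$denominator)
  out
}
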
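#' Construct a multi-tissue count table
#'
#' Bundles a genes x tissues matrix of unique-mapped read counts with the
#' per-tissue library sizes (total unique mapped reads). Library sizes are
#' carried as metadata rather than recomputed from the matrix because the
#' mapped-read total of a library normally exceeds the column sum over any
#' particular gene set.
#'
#' @param counts Numeric matrix of non-negative read counts. Row names are
#'   gene identifiers (required, unique); column names are tissue labels.
#' @param library_sizes Numeric vector of total unique mapped reads per
#'   tissue, one per column of `counts`. May be named; names must then match
#'   the column names.
#' @param warn_mismatch Warn when a library size differs from its column sum
#'   by more than 1%. Expected for real libraries (reads map outside the
#'   tested gene set); useful as a consistency check for simulated tables.
#' @return An object of class `count_table`: a list with elements `counts`
#'   and `library_sizes`.
#' @examples
#' m <- matrix(c(10, 0, 5, 7), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("MS", "MP")))
#' count_table(m, c(MS = 1e6, MP = 2e6))
#' @export
count_table <- function(counts, library_sizes, warn_mismatch = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("'counts' must be a numeric matrix")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stopf("'counts' must have unique row names (gene identifiers)")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("T", seq_len(ncol(counts)))
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("'counts' must be finite and non-negative")
  if (length(library_sizes) != ncol(counts))
    stopf("'library_sizes' must have one entry per tissue column")
  if (!is.null(names(library_sizes))) {
    if (!setequal(names(library_sizes), colnames(counts)))
      stopf("names of 'library_sizes' do not match tissue columns")
    library_sizes <- library_sizes[colnames(counts)]
  } else {
    names(library_sizes) <- colnames(counts)
  }
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    stopf("'library_sizes' must be positive")
  cs <- colSums(counts)
  if (any(cs > library_sizes + 1e-8)) {
    bad <- colnames(counts)[cs > library_sizes + 1e-8]
    stopf("library size smaller than column sum for: %s",
          paste(bad, collapse = ", "))
  }
  if (warn_mismatch) {
    rel <- abs(library_sizes - cs) / library_sizes
    if (any(rel > 0.01))
      warnf("library sizes differ >1%% from column sums for: %s",
            paste(colnames(counts)[rel > 0.01], collapse = ", "))
  }
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "count_table")
}

#' Longest-transcript length per gene
#'
#' Reduces transcript-level lengths to one length per gene by taking the
#' maximum, the convention used when a single representative length is needed
#' for RPKM.
#'
#' @param transcripts Data frame with columns `gene_id` and `length`
#'   (transcript length in bp); a `transcript_id` column is allowed and
#'   ignored.
#' @return Named numeric vector of gene lengths (bp).
#' @examples
#' longest_lengths(data.frame(gene_id = c("g1", "g1", "g2"),
#'                            length = c(1200, 800, 500)))
#' @export
longest_lengths <- function(transcripts) {
  if (!is.data.frame(transcripts) ||
      !all(c("gene_id", "length") %in% names(transcripts)))
    stopf("'transcripts' must be a data frame with columns gene_id, length")
  len <- transcripts$length
  ok <- is.finite(len) & len > 0
  res <- tapply(ifelse(ok, len, -Inf), transcripts$gene_id, max)
  bad <- names(res)[!is.finite(res)]
  if (length(bad))
    stopf("gene(s) with no positive-length transcript: %s",
          paste(utils::head(bad, 10), collapse = ", "))
  out <- as.numeric(res)
  names(out) <- names(res)
  out
}

#' Gene lengths from a GFF3 file
#'
#' Computes the length of each transcript as the sum of its exon lengths
#' (1-based inclusive coordinates) and keeps the longest transcript per gene.
#' Transcripts without exon children fall back to their genomic span.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon features linked by
#'   `ID`/`Parent` attributes.
#' @param strip_prefix Remove `"gene:"`/`"transcript:"`-style prefixes from
#'   feature identifiers (common in Ensembl GFF3).
#' @return Named numeric vector of gene lengths (bp), as [longest_lengths()].
#' @export
gff3_lengths <- function(path, strip_prefix = TRUE) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("gff3_lengths() requires the 'rtracklayer' package")
  gr <- rtracklayer::import(path, format = "gff3")
  clean <- function(x) if (strip_prefix) sub("^[A-Za-z_]+:", "", x) else x
  type <- as.character(gr$type)
  tx <- gr[type %in% c("mRNA", "transcript")]
  if (length(tx) == 0) stopf("no mRNA/transcript features in %s", path)
  tx_id <- clean(tx$ID)
  tx_gene <- clean(vapply(as.list(tx$Parent), `[`, character(1), 1L))
  # genomic span fallback, overridden by summed exon length where exons exist
  tx_len <- setNames(BiocGenerics::width(tx), tx_id)
  ex <- gr[type == "exon"]
  if (length(ex)) {
    par <- as.list(ex$Parent)
    nper <- lengths(par)
    ex_tx <- clean(unlist(par, use.names = FALSE))
    ex_w <- rep(BiocGenerics::width(ex), nper)
    exsum <- tapply(ex_w, ex_tx, sum)
    hit <- intersect(names(exsum), tx_id)
    tx_len[hit] <- exsum[hit]
  }
  longest_lengths(data.frame(gene_id = tx_gene, length = as.numeric(tx_len)))
}

#' RPKM normalization
#'
#' Reads Per Kilobase of transcript per Million mapped reads:
#' `RPKM = 1e9 * C / (N * L)` for count `C`, library size `N` (total unique
#' mapped reads) and gene length `L` in bp. Exact zeros in the counts stay
#' exact zeros.
#'
#' @param x A [count_table()].
#' @param lengths Named numeric vector of gene lengths in bp covering every
#'   gene in `x` (see [longest_lengths()]); genes missing a length are a hard
#'   error because silently dropping them corrupts downstream background
#'   totals.
#' @return Numeric matrix of RPKM values with the dimensions of `x$counts`.
#' @examples
#' m <- matrix(10, 1, 1, dimnames = list("g1", "MS"))
#' rpkm(count_table(m, 1e6), c(g1 = 1000))  # 10
#' @export
rpkm <- function(x, lengths) {
  stopifnot(inherits(x, "count_table"))
  missing <- setdiff(rownames(x$counts), names(lengths))
  if (length(missing))
    stopf("no length for gene(s): %s%s",
          paste(utils::head(missing, 10), collapse = ", "),
          if (length(missing) > 10) sprintf(" (and %d more)",
                                            length(missing) - 10) else "")
  L <- lengths[rownames(x$counts)]
  if (any(!is.finite(L)) || any(L <= 0)) stopf("gene lengths must be positive")
  out <- sweep(x$counts, 1, L, "/")
  out <- sweep(out, 2, x$library_sizes, "/") * 1e9
  out
}

#' Presence calls from counts per million
#'
#' A gene is called expressed in a tissue when its unique-mapped reads reach
#' the threshold in counts per million mapped reads:
#' `1e6 * C / N >= threshold_per_million`. The boundary is inclusive: a gene
#' with exactly four reads per million passes the default filter.
#'
#' @param x A [count_table()].
#' @param threshold_per_million Presence threshold in reads per million unique
#'   mapped reads (default 4).
#' @return Logical genes x tissues matrix.
#' @export
call_expressed <- function(x, threshold_per_million = 4) {
  stopifnot(inherits(x, "count_table"))
  if (!is.numeric(threshold_per_million) || threshold_per_million <= 0)
    stopf("'threshold_per_million' must be positive")
  cpm <- sweep(x$counts, 2, x$library_sizes / 1e6, "/")
  cpm >= threshold_per_million
}

#' Venn partition of presence calls
#'
#' Assigns every gene expressed in at least one tissue to exactly one of the
#' `2^T - 1` presence patterns and counts each region.
#'
#' @param calls Logical genes x tissues matrix from [call_expressed()].
#' @return Named integer vector over all non-empty tissue combinations
#'   (labels joined by `&`), summing to the number of genes expressed in at
#'   least one tissue.
#' @export
venn_partition <- function(calls) {
  if (!is.matrix(calls) || !is.logical(calls) || ncol(calls) < 2)
    stopf("'calls' must be a logical matrix with >= 2 tissue columns")
  tissues <- colnames(calls)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(tissues)))[-1, ,
                                                                    drop = FALSE]
  labels <- apply(combos, 1, function(r) paste(tissues[as.logical(r)],
                                               collapse = "&"))
  key <- apply(calls, 1, function(r) paste(tissues[r], collapse = "&"))
  tab <- table(factor(key[key != ""], levels = labels))
  out <- as.integer(tab)
  names(out) <- labels
  out
}

#' Genes specific to one tissue
#'
#' Returns the genes called expressed in the focal tissue and in no other
#' tissue.
#'
#' @param calls Logical genes x tissues matrix from [call_expressed()].
#' @param focal Focal tissue label.
#' @return Character vector of gene identifiers.
#' @export
call_specific <- function(calls, focal) {
  if (!is.matrix(calls) || !is.logical(calls))
    stopf("'calls' must be a logical matrix")
  if (!focal %in% colnames(calls))
    stopf("unknown tissue '%s'; tissues are: %s", focal,
          paste(colnames(calls), collapse = ", "))
  others <- setdiff(colnames(calls), focal)
  sel <- calls[, focal] & rowSums(calls[, others, drop = FALSE]) == 0
  rownames(calls)[sel]
}
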
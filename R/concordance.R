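# Correlation analyses between libraries (Pearson on clamped log2 RPKM) and
# between platforms (Spearman over shared genes).

#' Clamped log2 transform of expression values
#'
#' `log2(RPKM)` with negative results set to zero, so values below 1 RPKM map
#' to 0 and exact zeros stay 0. This keeps low-abundance noise from dominating
#' Pearson correlations between libraries.
#'
#' @param x Non-negative numeric vector or matrix of expression values.
#' @return Object of the same shape with `max(0, log2(x))` entries.
#' @examples
#' log2_clamped(c(0, 0.5, 1, 8))  # 0 0 0 3
#' @export
log2_clamped <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stopf("expression values must be >= 0")
  out <- x
  out[] <- ifelse(x > 0, pmax(log2(x), 0), 0)
  out
}

#' Pearson correlation matrix between samples
#'
#' Pairwise Pearson correlation of sample columns, by default over the genes
#' with a nonzero value in at least one sample (the genes expressed
#' somewhere); samples with zero variance over that universe are an error.
#'
#' @param scores Genes x samples numeric matrix, typically clamped log2 RPKM
#'   from [log2_clamped()].
#' @param genes `"nonzero"` (default) to use genes with a nonzero value in at
#'   least one sample, or `"all"`.
#' @return Symmetric samples x samples correlation matrix with unit diagonal.
#' @export
pcc_matrix <- function(scores, genes = c("nonzero", "all")) {
  genes <- match.arg(genes)
  if (!is.matrix(scores) || nrow(scores) < 2)
    stopf("'scores' must be a matrix with >= 2 genes")
  if (genes == "nonzero")
    scores <- scores[rowSums(scores != 0) > 0, , drop = FALSE]
  v <- apply(scores, 2, sd)
  if (any(v == 0))
    stopf("zero-variance sample(s): %s",
          paste(colnames(scores)[v == 0], collapse = ", "))
  cor(scores)
}

#' Spearman correlation per sample pair across two platforms
#'
#' For every sample present in both matrices, computes the Spearman rank
#' correlation (Pearson on mid-ranks, ties averaged) over the shared genes.
#' Rank correlation absorbs the scale discrepancy between platforms such as
#' RNA-seq RPKM and microarray intensities.
#'
#' @param a,b Genes x samples numeric matrices with gene row names and sample
#'   column names.
#' @param shared_genes Optional character vector of genes to use; defaults to
#'   all genes common to `a` and `b`. Fewer than 3 shared genes is an error.
#' @return Named numeric vector of Spearman coefficients, one per shared
#'   sample.
#' @export
scc_pairs <- function(a, b, shared_genes = NULL) {
  if (is.null(rownames(a)) || is.null(rownames(b)))
    stopf("'a' and 'b' must have gene row names")
  shared <- shared_genes %||% intersect(rownames(a), rownames(b))
  shared <- intersect(intersect(shared, rownames(a)), rownames(b))
  if (length(shared) < 3)
    stopf("need at least 3 shared genes, have %d", length(shared))
  samples <- intersect(colnames(a), colnames(b))
  if (!length(samples)) stopf("no sample columns in common")
  vapply(samples, function(s)
    cor(a[shared, s], b[shared, s], method = "spearman"),
    numeric(1))
}
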
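#' Audic-Claverie exact test for two sequencing libraries
#'
#' Exact significance test for comparing the read count of a gene between two
#' unreplicated libraries of sizes `n1` and `n2`. Conditional on observing
#' `x` reads in library 1, the count in library 2 under the null hypothesis of
#' equal underlying rates follows
#' `p(y | x) = (n2/n1)^y * (x+y)! / (x! * y! * (1 + n2/n1)^(x+y+1))`,
#' which is the negative binomial distribution with size `x + 1` and success
#' probability `n1 / (n1 + n2)`; tail probabilities are evaluated through that
#' identity, which is numerically stable up to library-scale counts.
#'
#' The two-sided p-value doubles the smaller conditional tail and caps at 1.
#' The test conditions on the observation with the larger normalized count
#' (`x/n1` vs `y/n2`), which makes the two-sided p-value exactly symmetric:
#' `ac_pvalue(x, y, n1, n2) == ac_pvalue(y, x, n2, n1)`.
#'
#' @param x,y Non-negative integer read counts in libraries 1 and 2
#'   (vectorized, recycled).
#' @param n1,n2 Library sizes (total unique mapped reads), positive.
#' @param alternative `"two.sided"` (default) or `"greater"` for the
#'   one-sided test that library 1's rate exceeds library 2's
#'   (`P(Y <= y | x)`, conditioning on `x`).
#' @return p-values in (0, 1].
#' @examples
#' ac_pvalue(10, 0, 1e6, 1e6)  # 2 / 2^11
#' ac_pvalue(5, 5, 1e6, 1e6)   # 1: equal counts at equal depth
#' @export
ac_pvalue <- function(x, y, n1, n2, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  if (any(x < 0) || any(y < 0) || any(x != round(x)) || any(y != round(y)))
    stopf("'x' and 'y' must be non-negative integer counts")
  if (any(n1 <= 0) || any(n2 <= 0)) stopf("library sizes must be positive")
  if (alternative == "greater") {
    return(pnbinom(y, size = x + 1, prob = n1 / (n1 + n2)))
  }
  swap <- x / n1 < y / n2
  xs <- ifelse(swap, y, x)
  ys <- ifelse(swap, x, y)
  pr <- ifelse(swap, n2, n1) / (n1 + n2)
  lower <- pnbinom(ys, size = xs + 1, prob = pr)
  upper <- ifelse(ys == 0, 1,
                  pnbinom(pmax(ys - 1, 0), size = xs + 1, prob = pr,
                          lower.tail = FALSE))
  pmin(1, 2 * pmin(lower, upper))
}

#' False discovery rate q-values
#'
#' Step-up FDR adjustment of a p-value vector: Benjamini-Hochberg by default,
#' Benjamini-Yekutieli (dependency-adjusted) by flag. Thin validated wrapper
#' around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"BY"`.
#' @return q-values, order-preserving and elementwise `>= p`.
#' @export
bh_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1)))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Per-gene fold change between two tissues
#'
#' Ratio of focal to other expression with a small floor on the denominator so
#' that genes absent from the other tissue get a large finite ratio instead of
#' `Inf`. The floor (default 1e-3 RPKM) is far below any expressed gene's
#' value, so it never affects genes passing the presence filter.
#'
#' @param expr Genes x tissues expression matrix (RPKM), as from [rpkm()].
#' @param focal,other Tissue column labels.
#' @param epsilon Denominator floor (default `1e-3`).
#' @return Named numeric vector of fold changes (>= 0, finite).
#' @export
fold_change <- function(expr, focal, other, epsilon = 1e-3) {
  for (t in c(focal, other))
    if (!t %in% colnames(expr)) stopf("unknown tissue '%s'", t)
  expr[, focal] / pmax(expr[, other], epsilon)
}

#' Criteria for calling preferential expression
#'
#' @param min_fold Minimum fold change, focal over other (default 2).
#' @param max_p Maximum raw p-value (default 1e-05).
#' @param max_fdr Maximum FDR q-value (default 1e-05).
#' @return A validated `preferential_criteria` list.
#' @export
preferential_criteria <- function(min_fold = 2, max_p = 1e-05,
                                  max_fdr = 1e-05) {
  check_field(min_fold, "min_fold",
              is.numeric(min_fold) && length(min_fold) == 1 && min_fold > 0,
              "a positive number")
  check_field(max_p, "max_p",
              is.numeric(max_p) && length(max_p) == 1 && max_p > 0,
              "a positive number")
  check_field(max_fdr, "max_fdr",
              is.numeric(max_fdr) && length(max_fdr) == 1 && max_fdr > 0,
              "a positive number")
  structure(list(min_fold = min_fold, max_p = max_p, max_fdr = max_fdr),
            class = "preferential_criteria")
}

#' Call genes preferentially expressed in one tissue
#'
#' Runs the Audic-Claverie test for the focal tissue against every other
#' tissue and returns the genes that are expressed in the focal tissue, are
#' not already tissue-specific (see [call_specific()]), and pass
#' `fold_change >= min_fold`, `p < max_p` and `q < max_fdr` in *every*
#' focal-vs-other comparison. The FDR family for each comparison is the set
#' of genes expressed in at least one member of the pair, mirroring the
#' presence pre-filter applied before testing.
#'
#' @param counts A [count_table()].
#' @param expr RPKM matrix from [rpkm()] on the same genes/tissues.
#' @param calls Presence matrix from [call_expressed()].
#' @param focal Focal tissue label.
#' @param criteria A [preferential_criteria()] object.
#' @param fdr_method FDR procedure, `"BH"` (default) or `"BY"`.
#' @param pool Compute the FDR over all comparisons pooled instead of within
#'   each comparison (default `FALSE`).
#' @param epsilon Fold-change denominator floor, see [fold_change()].
#' @return A `preferential_call` object: list with `genes` (character),
#'   `records` (one data frame row per gene x comparison: `gene_id`,
#'   `comparison`, `x`, `y`, `fold_change`, `p_value`, `q_value`, `pass`),
#'   `focal`, `criteria`, `fdr_method`, `pooled`.
#' @export
call_preferential <- function(counts, expr, calls, focal,
                              criteria = preferential_criteria(),
                              fdr_method = c("BH", "BY"), pool = FALSE,
                              epsilon = 1e-3) {
  stopifnot(inherits(counts, "count_table"),
            inherits(criteria, "preferential_criteria"))
  fdr_method <- match.arg(fdr_method)
  tissues <- colnames(counts$counts)
  if (!focal %in% tissues) stopf("unknown tissue '%s'", focal)
  others <- setdiff(tissues, focal)
  if (!length(others)) stopf("need at least two tissues")
  specific <- call_specific(calls, focal)
  N <- counts$library_sizes

  recs <- lapply(others, function(t) {
    fam <- rownames(counts$counts)[calls[, focal] | calls[, t]]
    data.frame(
      gene_id = fam,
      comparison = paste0(focal, "_vs_", t),
      x = counts$counts[fam, focal],
      y = counts$counts[fam, t],
      fold_change = unname(fold_change(expr, focal, t, epsilon)[fam]),
      p_value = ac_pvalue(counts$counts[fam, focal], counts$counts[fam, t],
                          N[focal], N[t]),
      row.names = NULL
    )
  })
  if (pool) {
    all_rec <- do.call(rbind, recs)
    all_rec$q_value <- bh_fdr(all_rec$p_value, fdr_method)
  } else {
    for (i in seq_along(recs))
      recs[[i]]$q_value <- bh_fdr(recs[[i]]$p_value, fdr_method)
    all_rec <- do.call(rbind, recs)
  }
  all_rec$pass <- all_rec$fold_change >= criteria$min_fold &
    all_rec$p_value < criteria$max_p & all_rec$q_value < criteria$max_fdr

  in_focal <- rownames(calls)[calls[, focal]]
  npass <- tapply(all_rec$pass, all_rec$gene_id, sum)
  everywhere <- names(npass)[npass == length(others)]
  genes <- setdiff(intersect(everywhere, in_focal), specific)
  genes <- genes[order(match(genes, rownames(counts$counts)))]

  structure(list(genes = genes, records = all_rec, focal = focal,
                 criteria = criteria, fdr_method = fdr_method, pooled = pool),
            class = "preferential_call")
}

#' Fold-change-only preferential call
#'
#' The simpler rule used for cross-dataset comparisons: a gene is preferential
#' when its focal-tissue abundance strictly exceeds `min_fold` times its
#' abundance in every other tissue. No significance test is involved.
#'
#' @param expr Genes x tissues expression matrix (RPKM).
#' @param focal Focal tissue label.
#' @param min_fold Fold threshold (default 2).
#' @return Character vector of gene identifiers.
#' @export
call_preferential_fold_only <- function(expr, focal, min_fold = 2) {
  if (!focal %in% colnames(expr)) stopf("unknown tissue '%s'", focal)
  others <- setdiff(colnames(expr), focal)
  ok <- rep(TRUE, nrow(expr))
  for (t in others) ok <- ok & expr[, focal] > min_fold * expr[, t]
  rownames(expr)[ok]
}
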
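#' Term annotation as flat gene sets
#'
#' Terms are treated as flat sets of annotated genes over a background
#' universe; no ontology structure is interpreted. The universe defaults to
#' every gene appearing in the annotation table.
#'
#' @param x Data frame whose first two columns are `gene_id` and `term_id`
#'   (column names are not required to match).
#' @param universe Optional character vector of background genes; must cover
#'   every annotated gene.
#' @return A `term_annotation` object: list with `sets` (named list of gene
#'   vectors per term) and `universe`.
#' @export
term_annotation <- function(x, universe = NULL) {
  if (!is.data.frame(x) || ncol(x) < 2)
    stopf("'x' must be a data frame with gene_id and term_id columns")
  gene <- as.character(x[[1]])
  term <- as.character(x[[2]])
  universe <- unique(as.character(universe %||% gene))
  if (!length(universe)) stopf("empty gene universe")
  outside <- setdiff(gene, universe)
  if (length(outside))
    stopf("%d annotated gene(s) not in the universe, e.g. %s",
          length(outside), outside[1])
  sets <- lapply(split(gene, term), unique)
  structure(list(sets = sets, universe = universe), class = "term_annotation")
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing at
#' least `k` annotated genes in a query of size `n` drawn from a universe of
#' `N` genes of which `K` carry the term. This is the one-tailed Fisher exact
#' p-value for over-representation. Evaluated via [stats::phyper()], which
#' works in log space internally.
#'
#' @param k Query genes carrying the term ("query item").
#' @param n Query size ("query total").
#' @param K Background genes carrying the term ("bg item").
#' @param N Universe size ("bg total").
#' @return p-values in (0, 1]. All arguments are vectorized.
#' @examples
#' hypergeom_tail(2, 3, 4, 10)  # 1/3 by enumeration
#' @export
hypergeom_tail <- function(k, n, K, N) {
  m <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(k, m); n <- rep_len(n, m)
  K <- rep_len(K, m); N <- rep_len(N, m)
  if (any(k < 0) || any(k > pmin(n, K)) || any(n > N) || any(K > N))
    stopf("inconsistent arguments: need 0 <= k <= min(n, K) and n, K <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Singular enrichment analysis of a gene set
#'
#' Tests every term with at least one query gene for over-representation
#' with the upper-tail hypergeometric probability, adjusts over all tested
#' terms with a step-up FDR procedure, and flags terms significant when
#' `p < p_cut` and `q <= fdr_cut`. The dependency-adjusted
#' Benjamini-Yekutieli procedure is the default, with plain
#' Benjamini-Hochberg by flag.
#'
#' @param query Character vector of query gene identifiers. Genes outside the
#'   annotation universe are dropped with a warning.
#' @param annotation A [term_annotation()].
#' @param p_cut Raw p-value cutoff (default 0.001).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @param fdr_method `"BY"` (default) or `"BH"`.
#' @return Data frame sorted by ascending p-value with columns `term_id`,
#'   `k`, `n`, `K`, `N`, `p_value`, `q_value`, `significant`.
#' @export
sea_enrich <- function(query, annotation, p_cut = 0.001, fdr_cut = 0.05,
                       fdr_method = c("BY", "BH")) {
  stopifnot(inherits(annotation, "term_annotation"))
  fdr_method <- match.arg(fdr_method)
  universe <- annotation$universe
  if (!length(universe)) stopf("empty gene universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("dropping %d query gene(s) outside the annotation universe",
          length(outside))
    query <- setdiff(query, outside)
  }
  n <- length(query)
  N <- length(universe)
  k <- vapply(annotation$sets, function(s) length(intersect(s, query)),
              integer(1))
  K <- lengths(annotation$sets)
  keep <- k >= 1
  out <- data.frame(term_id = names(annotation$sets)[keep],
                    k = unname(k[keep]), n = n,
                    K = unname(K[keep]), N = N, row.names = NULL)
  out$p_value <- hypergeom_tail(out$k, out$n, out$K, out$N)
  out$q_value <- bh_fdr(out$p_value, fdr_method)
  out$significant <- out$p_value < p_cut & out$q_value <= fdr_cut
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' PAGE z-scores for gene sets
#'
#' Parametric analysis of gene-set enrichment: for a per-gene score vector
#' (typically a log2 fold change between two conditions) with overall mean
#' `mu` and standard deviation `delta`, a set of `m` genes with mean score
#' `Sm` gets `Z = (Sm - mu) * sqrt(m) / delta`, compared against the standard
#' normal.
#'
#' @param scores Named numeric vector of per-gene scores covering the genes
#'   to be analysed (at least 2).
#' @param annotation A [term_annotation()]; each term is scored over its
#'   genes present in `scores`.
#' @return Data frame with columns `term_id`, `m`, `Sm`, `mu`, `delta`, `Z`,
#'   `p_value` (two-sided normal), sorted by ascending p-value.
#' @export
page_zscores <- function(scores, annotation) {
  stopifnot(inherits(annotation, "term_annotation"))
  if (length(scores) < 2 || is.null(names(scores)))
    stopf("'scores' must be a named vector with >= 2 genes")
  mu <- mean(scores)
  delta <- sd(scores)
  if (!is.finite(delta) || delta == 0)
    stopf("gene scores have zero standard deviation")
  rows <- lapply(names(annotation$sets), function(term) {
    genes <- intersect(annotation$sets[[term]], names(scores))
    if (!length(genes)) return(NULL)
    m <- length(genes)
    Sm <- mean(scores[genes])
    Z <- (Sm - mu) * sqrt(m) / delta
    data.frame(term_id = term, m = m, Sm = Sm, mu = mu, delta = delta, Z = Z,
               p_value = 2 * pnorm(-abs(Z)), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
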
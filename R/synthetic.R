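#' Configuration for the synthetic count generator
#'
#' The defaults emulate the study design the package targets: four tissue
#' libraries (silk-like focal tissue plus pollen, ovary and seedling
#' stand-ins) of 6.1-6.8 million unique mapped reads each, with 725 planted
#' tissue-specific and 702 tissue-preferential genes among 20,000 genes of
#' which 10% are silent everywhere.
#'
#' Per-gene baseline expression rates (in reads per million) are drawn
#' log-normally; when `calibrate_depth` is `TRUE` they are rescaled so the
#' expected non-focal column total equals the configured library size.
#' Specific genes get rate zero outside the focal tissue and at least
#' `specific_min_cpm` reads per million inside; preferential genes have their
#' focal rate multiplied by `preferential_fold`. Counts are Poisson when
#' `dispersion = 0` and negative binomial with variance `mu + dispersion *
#' mu^2` otherwise.
#'
#' @param n_genes Number of genes.
#' @param tissue_names Ordered tissue labels; the first is the focal tissue.
#' @param library_sizes Target total reads per tissue.
#' @param length_range Min/max gene length in bp (lengths drawn uniformly).
#' @param n_specific,n_preferential Planted gene counts.
#' @param preferential_fold Focal-over-other mean ratio for preferential
#'   genes (>= 1).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters (natural
#'   log, reads-per-million scale) of the baseline rate draw.
#' @param dispersion Negative-binomial dispersion alpha >= 0 (0 = Poisson).
#' @param silent_fraction Fraction of genes with expected count 0 everywhere,
#'   giving the presence filter true negatives.
#' @param specific_min_cpm Floor (reads per million) on the focal-tissue rate
#'   of planted specific genes, keeping them comfortably above the presence
#'   threshold.
#' @param calibrate_depth Rescale baseline rates so expected column totals
#'   match `library_sizes`.
#' @param seed Integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 20000,
                       tissue_names = c("MS", "MP", "MO", "SL"),
                       library_sizes = c(6500000, 6145170, 6764608, 6300000),
                       length_range = c(200, 5000),
                       n_specific = 725, n_preferential = 702,
                       preferential_fold = 8,
                       baseline_log_mean = log(50), baseline_log_sd = 1,
                       dispersion = 0, silent_fraction = 0.1,
                       specific_min_cpm = 20, calibrate_depth = TRUE,
                       seed = 1) {
  check_field(n_genes, "n_genes", is_count_scalar(n_genes) && n_genes > 0,
              "a positive integer")
  check_field(tissue_names, "tissue_names",
              is.character(tissue_names) && length(tissue_names) >= 2 &&
                !anyDuplicated(tissue_names), ">= 2 unique labels")
  check_field(library_sizes, "library_sizes",
              is.numeric(library_sizes) &&
                length(library_sizes) == length(tissue_names) &&
                all(library_sizes > 0), "positive, one per tissue")
  check_field(length_range, "length_range",
              is.numeric(length_range) && length(length_range) == 2 &&
                length_range[1] > 0 && length_range[1] <= length_range[2],
              "positive ascending min/max in bp")
  check_field(n_specific, "n_specific", is_count_scalar(n_specific),
              "a non-negative integer")
  check_field(n_preferential, "n_preferential",
              is_count_scalar(n_preferential), "a non-negative integer")
  check_field(preferential_fold, "preferential_fold",
              is.numeric(preferential_fold) && preferential_fold >= 1,
              ">= 1")
  check_field(dispersion, "dispersion",
              is.numeric(dispersion) && length(dispersion) == 1 &&
                dispersion >= 0, ">= 0")
  check_field(baseline_log_sd, "baseline_log_sd",
              is.numeric(baseline_log_sd) && baseline_log_sd >= 0, ">= 0")
  check_field(silent_fraction, "silent_fraction",
              is.numeric(silent_fraction) && silent_fraction >= 0 &&
                silent_fraction < 1, "in [0, 1)")
  check_field(specific_min_cpm, "specific_min_cpm",
              is.numeric(specific_min_cpm) && specific_min_cpm >= 0, ">= 0")
  check_field(seed, "seed", is.numeric(seed) && length(seed) == 1,
              "a single integer")
  n_silent <- round(silent_fraction * n_genes)
  if (n_specific + n_preferential > n_genes - n_silent)
    stopf("invalid 'n_specific'/'n_preferential': %d + %d planted genes exceed the %d non-silent genes",
          n_specific, n_preferential, n_genes - n_silent)
  structure(list(n_genes = n_genes, tissue_names = tissue_names,
                 library_sizes = setNames(library_sizes, tissue_names),
                 length_range = length_range, n_specific = n_specific,
                 n_preferential = n_preferential,
                 preferential_fold = preferential_fold,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, dispersion = dispersion,
                 silent_fraction = silent_fraction,
                 specific_min_cpm = specific_min_cpm,
                 calibrate_depth = calibrate_depth, seed = seed),
            class = "sim_config")
}

#' Simulate a multi-tissue count table with planted structure
#'
#' Draws per-gene counts under the model described in [sim_config()] and
#' returns the count table together with gene lengths and the ground-truth
#' labels of every gene. The library sizes attached to the returned count
#' table are the *realized* column sums, so downstream normalization sees
#' self-consistent totals. Identical configuration (including seed) gives
#' bitwise-identical output; the caller's RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_counts` with elements `counts` (a
#'   [count_table()]), `lengths` (named bp vector), `truth` (data frame
#'   `gene_id`, `label` with levels specific/preferential/background/silent),
#'   `rates` (expected reads-per-million matrix) and `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_genes
    tn <- cf$tissue_names
    ids <- sprintf("g%05d", seq_len(n))
    n_silent <- round(cf$silent_fraction * n)
    lab <- rep("background", n)
    shuffled <- sample.int(n)
    take <- function(k, from) shuffled[seq_len(k) + from]
    if (n_silent > 0) lab[take(n_silent, 0)] <- "silent"
    if (cf$n_specific > 0) lab[take(cf$n_specific, n_silent)] <- "specific"
    if (cf$n_preferential > 0)
      lab[take(cf$n_preferential, n_silent + cf$n_specific)] <- "preferential"

    base <- rlnorm(n, cf$baseline_log_mean, cf$baseline_log_sd)
    base[lab == "silent"] <- 0
    if (cf$calibrate_depth && sum(base) > 0) base <- base / sum(base) * 1e6

    rates <- matrix(base, n, length(tn), dimnames = list(ids, tn))
    focal <- tn[1]
    spec <- lab == "specific"
    rates[spec, setdiff(tn, focal)] <- 0
    rates[spec, focal] <- pmax(base[spec], cf$specific_min_cpm)
    pref <- lab == "preferential"
    rates[pref, focal] <- base[pref] * cf$preferential_fold

    mu <- sweep(rates, 2, cf$library_sizes / 1e6, "*")
    cnt <- if (cf$dispersion == 0) rpois(length(mu), mu)
           else rnbinom(length(mu), mu = mu, size = 1 / cf$dispersion)
    counts <- matrix(cnt, n, length(tn), dimnames = dimnames(mu))
    lengths <- setNames(round(runif(n, cf$length_range[1],
                                    cf$length_range[2])), ids)

    structure(list(
      counts = count_table(counts, colSums(counts)),
      lengths = lengths,
      truth = data.frame(gene_id = ids,
                         label = factor(lab, levels = c("specific",
                                                        "preferential",
                                                        "background",
                                                        "silent"))),
      rates = rates, config = cf), class = "sim_counts")
  })
}

#' Simulate a tabular alignment hit file with known best hits
#'
#' Plants, for exactly `n_matched` focal genes, a true best hit (lowest
#' E-value, drawn log-uniformly within `e_range`) to a designated
#' other-species gene. Some matched genes additionally receive weaker
#' qualifying hits (E-value between the true hit's and 1e-10) to exercise
#' best-hit selection, and decoy hits with E-value above 1e-10 are spread
#' over random queries.
#'
#' @param focal_ids,other_ids Character vectors of query and subject
#'   identifiers.
#' @param n_matched Number of focal genes that must receive a qualifying hit
#'   (`<= min(length(focal_ids), length(other_ids))`).
#' @param e_range Range of true-hit E-values; must lie within (0, 1e-10] so
#'   planted hits qualify under the default homolog cutoff.
#' @param seed Integer RNG seed.
#' @param extra_hit_prob Probability that a matched gene also gets a weaker
#'   qualifying hit to a different subject.
#' @param n_decoys Number of non-qualifying decoy rows (E-value > 1e-10).
#' @return List of class `sim_hits` with `hits` (12-column outfmt-6-style
#'   data frame) and `truth` (data frame `query_id`, `subject_id` of the
#'   planted best hits).
#' @export
simulate_hits <- function(focal_ids, other_ids, n_matched,
                          e_range = c(1e-100, 1e-11), seed = 1,
                          extra_hit_prob = 0.4,
                          n_decoys = round(length(focal_ids) / 4)) {
  check_field(n_matched, "n_matched",
              is_count_scalar(n_matched) &&
                n_matched <= min(length(focal_ids), length(other_ids)),
              "<= min(|focal_ids|, |other_ids|)")
  check_field(e_range, "e_range",
              is.numeric(e_range) && length(e_range) == 2 &&
                e_range[1] > 0 && e_range[1] <= e_range[2] &&
                e_range[2] <= 1e-10,
              "ascending within (0, 1e-10]")
  with_seed(seed, {
    row_of <- function(q, s, e) {
      if (!length(q))
        return(data.frame(qseqid = character(), sseqid = character(),
                          pident = numeric(), length = integer(),
                          mismatch = numeric(), gapopen = integer(),
                          qstart = integer(), qend = integer(),
                          sstart = integer(), send = integer(),
                          evalue = numeric(), bitscore = numeric()))
      len <- round(runif(length(q), 100, 500))
      data.frame(qseqid = q, sseqid = s,
                 pident = round(runif(length(q), 40, 95), 1), length = len,
                 mismatch = round(len * 0.1), gapopen = 1L, qstart = 1L,
                 qend = len, sstart = 1L, send = len, evalue = e,
                 bitscore = round(-2 * log10(e)) + 40)
    }
    mq <- sample(focal_ids, n_matched)
    ms <- sample(other_ids, n_matched)
    e_true <- 10^runif(n_matched, log10(e_range[1]), log10(e_range[2]))
    hits <- row_of(mq, ms, e_true)
    extra <- which(runif(n_matched) < extra_hit_prob)
    if (length(extra) && length(other_ids) > 1) {
      alt <- vapply(extra, function(i)
        sample(setdiff(other_ids, ms[i]), 1), character(1))
      # weaker than the true hit but still under the qualifying cutoff
      e_extra <- 10^runif(length(extra), log10(e_true[extra]), -10)
      hits <- rbind(hits, row_of(mq[extra], alt, e_extra))
    }
    if (n_decoys > 0) {
      dq <- sample(focal_ids, n_decoys, replace = TRUE)
      ds <- sample(other_ids, n_decoys, replace = TRUE)
      hits <- rbind(hits, row_of(dq, ds, 10^runif(n_decoys, -9, -1)))
    }
    hits <- hits[sample.int(nrow(hits)), , drop = FALSE]
    rownames(hits) <- NULL
    structure(list(hits = hits,
                   truth = data.frame(query_id = mq, subject_id = ms)),
              class = "sim_hits")
  })
}

#' Simulate a term annotation with one enriched term
#'
#' Assigns genes to terms independently at `base_rate`, except that
#' membership in `planted_term` is enriched in `query_set` by the stated odds
#' ratio: if the background membership odds are `o`, query genes join the
#' planted term with odds `enrichment_odds * o`. `enrichment_odds = 1` gives
#' a null annotation.
#'
#' @param genes Character vector of gene identifiers, or a single integer
#'   `n` (identifiers `g00001 ...` are generated).
#' @param n_terms Number of terms (`T001 ...`).
#' @param planted_term Term index or identifier carrying the enrichment.
#' @param query_set Genes in which the planted term is enriched (subset of
#'   `genes`).
#' @param enrichment_odds Odds multiplier >= 1.
#' @param base_rate Background membership probability per gene and term.
#' @param seed Integer RNG seed.
#' @return List of class `sim_annotation` with `annotation` (a
#'   [term_annotation()] over all `genes`), `table` (long `gene_id`,
#'   `term_id` data frame) and `planted_term`.
#' @export
simulate_annotation <- function(genes, n_terms, planted_term = 1, query_set,
                                enrichment_odds = 1, base_rate = 0.05,
                                seed = 1) {
  if (is.numeric(genes) && length(genes) == 1)
    genes <- sprintf("g%05d", seq_len(genes))
  terms <- sprintf("T%03d", seq_len(n_terms))
  if (is.numeric(planted_term)) planted_term <- terms[planted_term]
  check_field(planted_term, "planted_term", planted_term %in% terms,
              "one of the generated terms")
  check_field(enrichment_odds, "enrichment_odds",
              is.numeric(enrichment_odds) && enrichment_odds >= 1, ">= 1")
  check_field(base_rate, "base_rate", base_rate > 0 && base_rate < 1,
              "in (0, 1)")
  query_set <- unique(as.character(query_set))
  if (length(setdiff(query_set, genes)))
    stopf("invalid 'query_set': contains genes outside 'genes'")
  odds1 <- enrichment_odds * base_rate / (1 - base_rate)
  p_in <- odds1 / (1 + odds1)
  with_seed(seed, {
    rows <- lapply(terms, function(t) {
      p <- rep(base_rate, length(genes))
      if (t == planted_term) p[genes %in% query_set] <- p_in
      member <- runif(length(genes)) < p
      if (!any(member)) return(NULL)
      data.frame(gene_id = genes[member], term_id = t)
    })
    tab <- do.call(rbind, rows)
    structure(list(annotation = term_annotation(tab, universe = genes),
                   table = tab, planted_term = planted_term),
              class = "sim_annotation")
  })
}

#' Deterministic membership sets with prescribed partition sizes
#'
#' Builds a synthetic focal gene set and two best-hit maps whose conservation
#' partition has exactly the requested sizes; used for worked examples and
#' set-arithmetic checks.
#'
#' @param n_focal Focal set size.
#' @param n_a,n_b Number of focal genes with a hit in species A / B.
#' @param n_both Number of focal genes with hits in both (`<= min(n_a,
#'   n_b)`).
#' @param n_subj_a,n_subj_b Number of distinct matched subjects per species
#'   (subjects are recycled over queries).
#' @return List with `focal`, `map_a`, `map_b` (named character vectors).
#' @export
make_partition_sets <- function(n_focal, n_a, n_b, n_both,
                                n_subj_a = n_a, n_subj_b = n_b) {
  stopifnot(n_both <= min(n_a, n_b), n_a + n_b - n_both <= n_focal,
            n_subj_a <= n_a || n_a == 0, n_subj_b <= n_b || n_b == 0)
  focal <- sprintf("f%05d", seq_len(n_focal))
  a_queries <- focal[seq_len(n_a)]
  b_queries <- focal[c(seq_len(n_both),
                       if (n_b > n_both) n_a + seq_len(n_b - n_both))]
  map_a <- setNames(sprintf("ra%04d", rep_len(seq_len(max(n_subj_a, 1)),
                                              n_a)), a_queries)
  map_b <- setNames(sprintf("rb%04d", rep_len(seq_len(max(n_subj_b, 1)),
                                              n_b)), b_queries)
  if (n_a == 0) map_a <- setNames(character(), character())
  if (n_b == 0) map_b <- setNames(character(), character())
  list(focal = focal, map_a = map_a, map_b = map_b)
}
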
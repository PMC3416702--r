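# End-to-end orchestration: quantify -> specific -> DGE/preferential ->
# combined list -> enrichment -> homology -> concordance, with a
# machine-readable manifest and a worked-example verifier.

normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("'config' must be a list or a YAML file path")
  has_sim <- !is.null(config$sim)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs)
    stopf("config must supply exactly one of 'sim' or 'inputs'")
  defaults <- list(seed = 1, focal = NULL, presence_threshold = 4,
                   epsilon = 1e-3, dge_fdr_method = "BH",
                   pool_comparisons = FALSE,
                   criteria = list(min_fold = 2, max_p = 1e-05,
                                   max_fdr = 1e-05),
                   enrichment = list(p_cut = 0.001, fdr_cut = 0.05,
                                     fdr_method = "BY"),
                   homology = list(e_max = 1e-10, min_identity = NULL,
                                   size_a = NULL, size_b = NULL))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      miss <- setdiff(names(defaults[[nm]]), names(config[[nm]]))
      config[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  if (has_inputs) {
    paths <- unlist(config$inputs[c("counts", "lengths", "annotation",
                                    "hits_a", "hits_b", "set_a", "set_b")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stopf("input file(s) not found: %s", paste(missing, collapse = ", "))
  }
  config
}

run_stage <- function(name, quiet, expr) {
  if (!quiet) message("[", name, "]")
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full tissue-specificity pipeline
#'
#' Executes every stage on either simulated inputs (a `sim` block passed to
#' [sim_config()]) or user-supplied files (an `inputs` block with paths
#' `counts`, `lengths` and optionally `annotation`, `hits_a`/`hits_b`,
#' `set_a`/`set_b`), writes all result tables plus a manifest to `out_dir`,
#' and returns the results. Identical config and seed give bitwise-identical
#' outputs.
#'
#' Config keys (all thresholds are defaults, logged at run start): `seed`,
#' `focal` (default: first tissue), `presence_threshold` (reads per million),
#' `criteria` (`min_fold`, `max_p`, `max_fdr`), `dge_fdr_method`
#' (`BH`/`BY`), `pool_comparisons`, `epsilon`, `enrichment` (`p_cut`,
#' `fdr_cut`, `fdr_method`), `homology` (`e_max`, `min_identity`, `size_a`,
#' `size_b`), `out_dir`.
#'
#' @param config A list, or the path of a YAML file, as described above.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `silk_run`: list with `rpkm`, `calls`, `venn`,
#'   `specific`, `preferential` (a [call_preferential()] result), `combined`
#'   (data frame `gene_id`, `source`), `enrichment`, `partition`, `summary`,
#'   `pcc`, `truth` (simulation only), `manifest`, `focal`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  config <- normalize_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stopf("no 'out_dir' supplied")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL; annotation <- NULL; hits_a <- NULL; hits_b <- NULL
  set_a <- NULL; set_b <- NULL
  if (!is.null(config$sim)) {
    sim <- run_stage("simulate", quiet, {
      cf <- do.call(sim_config, c(config$sim,
                                  list(seed = config$seed)[is.null(config$sim$seed)]))
      simulate_counts(cf)
    })
    counts <- sim$counts
    lengths <- sim$lengths
    truth <- sim$truth
    planted <- as.character(truth$gene_id[truth$label %in%
                                            c("specific", "preferential")])
    ann <- run_stage("simulate_annotation", quiet,
      simulate_annotation(as.character(truth$gene_id), n_terms = 30,
                          planted_term = 1, query_set = planted,
                          enrichment_odds = 10, base_rate = 0.05,
                          seed = config$seed + 1))
    annotation <- ann$annotation
    ids <- as.character(truth$gene_id)
    ha <- run_stage("simulate_hits", quiet, list(
      a = simulate_hits(ids, sprintf("ra%05d", seq_len(length(ids))),
                        n_matched = round(length(ids) * 0.3),
                        seed = config$seed + 2),
      b = simulate_hits(ids, sprintf("rb%05d", seq_len(length(ids))),
                        n_matched = round(length(ids) * 0.12),
                        seed = config$seed + 3)))
    hits_a <- ha$a$hits; hits_b <- ha$b$hits
  } else {
    inp <- config$inputs
    counts <- run_stage("read_counts", quiet, {
      ls <- inp$library_sizes
      if (is.list(ls)) ls <- unlist(ls)
      read_count_table(inp$counts, ls)
    })
    lengths <- run_stage("read_lengths", quiet, {
      if (grepl("\\.gff3?(\\.gz)?$", inp$lengths)) gff3_lengths(inp$lengths)
      else read_gene_lengths(inp$lengths)
    })
    if (!is.null(inp$annotation))
      annotation <- run_stage("read_annotation", quiet,
                              read_term_annotation(inp$annotation))
    if (!is.null(inp$hits_a)) hits_a <- run_stage("read_hits_a", quiet,
                                                  read_hits(inp$hits_a))
    if (!is.null(inp$hits_b)) hits_b <- run_stage("read_hits_b", quiet,
                                                  read_hits(inp$hits_b))
    if (!is.null(inp$set_a)) set_a <- read_gene_set(inp$set_a)
    if (!is.null(inp$set_b)) set_b <- read_gene_set(inp$set_b)
  }
  tissues <- colnames(counts$counts)
  focal <- config$focal %||% tissues[1]
  if (!focal %in% tissues) stopf("focal tissue '%s' not among: %s", focal,
                                 paste(tissues, collapse = ", "))
  if (!quiet)
    message("thresholds: presence >= ", config$presence_threshold,
            " per million; fold >= ", config$criteria$min_fold,
            "; p < ", config$criteria$max_p,
            "; FDR < ", config$criteria$max_fdr,
            " (", config$dge_fdr_method, ")")

  expr <- run_stage("rpkm", quiet, rpkm(counts, lengths))
  calls <- run_stage("presence_filter", quiet,
                     call_expressed(counts, config$presence_threshold))
  venn <- venn_partition(calls)
  specific <- run_stage("specific", quiet, call_specific(calls, focal))
  pref <- run_stage("preferential", quiet,
    call_preferential(counts, expr, calls, focal,
                      criteria = do.call(preferential_criteria,
                                         config$criteria),
                      fdr_method = config$dge_fdr_method,
                      pool = isTRUE(config$pool_comparisons),
                      epsilon = config$epsilon))
  combined <- data.frame(
    gene_id = c(specific, pref$genes),
    source = rep(c("specific", "preferential"),
                 c(length(specific), length(pref$genes))))
  stopifnot(!anyDuplicated(combined$gene_id),
            nrow(combined) == length(specific) + length(pref$genes),
            all(combined$gene_id %in% rownames(calls)[calls[, focal]]))

  enrichment <- NULL
  if (!is.null(annotation) && nrow(combined))
    enrichment <- run_stage("enrichment", quiet,
      sea_enrich(combined$gene_id, annotation,
                 p_cut = config$enrichment$p_cut,
                 fdr_cut = config$enrichment$fdr_cut,
                 fdr_method = config$enrichment$fdr_method))
  partition <- NULL; summary_df <- NULL
  if (!is.null(hits_a) && !is.null(hits_b) && nrow(combined)) {
    partition <- run_stage("homology", quiet, {
      bh_a <- best_hits(hits_a, subject_filter = set_a,
                        e_max = config$homology$e_max,
                        min_identity = config$homology$min_identity)
      bh_b <- best_hits(hits_b, subject_filter = set_b,
                        e_max = config$homology$e_max,
                        min_identity = config$homology$min_identity)
      conservation_partition(combined$gene_id, bh_a, bh_b)
    })
    summary_df <- partition_summary(partition, config$homology$size_a,
                                    config$homology$size_b)
  }
  pcc <- run_stage("concordance", quiet, pcc_matrix(log2_clamped(expr)))

  recovery <- NULL
  if (!is.null(truth)) {
    planted_spec <- as.character(truth$gene_id[truth$label == "specific"])
    planted_pref <- as.character(truth$gene_id[truth$label == "preferential"])
    recovery <- list(
      specific_sensitivity =
        length(intersect(specific, planted_spec)) / max(1, length(planted_spec)),
      specific_false = length(setdiff(specific, planted_spec)),
      preferential_sensitivity =
        length(intersect(pref$genes, planted_pref)) /
          max(1, length(planted_pref)),
      preferential_fdp =
        length(setdiff(pref$genes, planted_pref)) / max(1, length(pref$genes)))
  }

  manifest <- list(
    package = "tissuespec",
    version = as.character(utils::packageVersion("tissuespec")),
    seed = config$seed, focal = focal,
    config = config[c("presence_threshold", "criteria", "dge_fdr_method",
                      "pool_comparisons", "epsilon", "enrichment",
                      "homology")],
    library_sizes = as.list(counts$library_sizes),
    venn = as.list(venn),
    row_counts = list(
      genes = nrow(counts$counts),
      expressed_focal = sum(calls[, focal]),
      expressed_per_tissue = as.list(colSums(calls)),
      specific = length(specific),
      preferential = length(pref$genes),
      combined = nrow(combined),
      enriched_terms = if (is.null(enrichment)) NULL
                       else sum(enrichment$significant),
      distinct = if (is.null(partition)) NULL
                 else length(partition$distinct)),
    recovery = recovery)

  run_stage("write_outputs", quiet, {
    write_tsv(data.frame(gene_id = rownames(expr), round(expr, 4),
                         check.names = FALSE),
              file.path(out_dir, "rpkm.tsv"))
    write_tsv(data.frame(region = names(venn), genes = venn),
              file.path(out_dir, "venn.tsv"))
    write_tsv(data.frame(gene_id = specific, tissue = focal),
              file.path(out_dir, "specific.tsv"))
    write_tsv(pref$records, file.path(out_dir, "dge_records.tsv"))
    write_tsv(data.frame(gene_id = pref$genes, tissue = focal),
              file.path(out_dir, "preferential.tsv"))
    write_tsv(combined, file.path(out_dir, "combined.tsv"))
    if (!is.null(enrichment))
      write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
    if (!is.null(partition)) {
      memb <- data.frame(
        gene_id = c(partition$hit_both, partition$hit_a_only,
                    partition$hit_b_only, partition$distinct),
        subset = rep(c("hit_both", "hit_a_only", "hit_b_only", "distinct"),
                     c(length(partition$hit_both),
                       length(partition$hit_a_only),
                       length(partition$hit_b_only),
                       length(partition$distinct))))
      write_tsv(memb, file.path(out_dir, "homology_partition.tsv"))
      write_tsv(summary_df, file.path(out_dir, "homology_summary.tsv"))
    }
    write_tsv(data.frame(sample = rownames(pcc), round(pcc, 6),
                         check.names = FALSE),
              file.path(out_dir, "pcc.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  })

  invisible(structure(list(rpkm = expr, calls = calls, venn = venn,
                           specific = specific, preferential = pref,
                           combined = combined, enrichment = enrichment,
                           partition = partition, summary = summary_df,
                           pcc = pcc, truth = truth, manifest = manifest,
                           focal = focal, out_dir = out_dir),
                      class = "silk_run"))
}

#' Recompute the packaged worked examples
#'
#' Recomputes, from the packaged reference tables and from closed-form
#' fixtures, the published quantities this pipeline can check at a desk:
#' the singular-enrichment p-values for every row of the bundled
#' contingency tables (compared at two significant figures against the
#' printed values), the cross-species set arithmetic and percentages, the
#' specific/preferential bookkeeping identity, and exact small examples of
#' the Audic-Claverie and hypergeometric tails. Failures are reported, not
#' raised.
#'
#' @param enrichment_table Path to a contingency-table TSV in the packaged
#'   format (default: the bundled tables).
#' @param set_sizes Named numeric vector of published set sizes (default:
#'   the bundled values); names as in
#'   `inst/extdata/published_set_sizes.tsv`.
#' @return Data frame of class `worked_examples` with columns `group`,
#'   `check`, `expected`, `computed`, `pass`.
#' @export
verify_worked_examples <- function(enrichment_table = NULL,
                                   set_sizes = NULL) {
  enrichment_table <- enrichment_table %||%
    system.file("extdata", "go_enrichment_tables.tsv",
                package = "tissuespec", mustWork = TRUE)
  if (is.null(set_sizes)) {
    ss <- read.delim(system.file("extdata", "published_set_sizes.tsv",
                                 package = "tissuespec", mustWork = TRUE))
    set_sizes <- setNames(ss$value, ss$quantity)
  }
  sig2 <- function(x) signif(x, 2)
  rows <- list()
  add <- function(group, check, expected, computed,
                  pass = isTRUE(all.equal(expected, computed,
                                          tolerance = 1e-9)))
    rows[[length(rows) + 1]] <<- data.frame(group = group, check = check,
                                            expected = expected,
                                            computed = computed, pass = pass)

  tab <- read.delim(enrichment_table)
  p <- hypergeom_tail(tab$query_item, tab$query_total, tab$bg_item,
                      tab$bg_total)
  for (i in seq_len(nrow(tab)))
    add("enrichment", sprintf("%s: %s", tab$gene_set[i], tab$term[i]),
        tab$p_printed[i], p[i], sig2(p[i]) == sig2(tab$p_printed[i]))

  sets <- make_partition_sets(set_sizes[["combined_focal"]],
                              set_sizes[["matched_in_rice"]],
                              set_sizes[["matched_in_arabidopsis"]],
                              set_sizes[["matched_in_both"]],
                              n_subj_a = set_sizes[["rice_subjects"]],
                              n_subj_b = set_sizes[["arabidopsis_subjects"]])
  part <- conservation_partition(sets$focal, sets$map_a, sets$map_b)
  summ <- partition_summary(part, size_a = set_sizes[["rice_dataset_size"]],
                            size_b = set_sizes[["arabidopsis_dataset_size"]])
  # expectations are the published counts and percentages themselves
  pick <- function(s, col) summ[[col]][summ$subset == s]
  add("set_arithmetic", "distinct genes", 923, length(part$distinct))
  add("set_arithmetic", "hit A (rice) only", 364, length(part$hit_a_only))
  add("set_arithmetic", "specific + preferential = combined", 1427,
      length(part$focal))
  add("set_arithmetic", "rice subjects % of rice dataset", 38.87,
      pick("subjects_a", "percent"))
  add("set_arithmetic", "Arabidopsis-matched % of focal", 9.81,
      pick("hit_b", "percent"))

  add("exact_tests", "AC two-sided, x=10 y=0 equal depth",
      2 / 2^11, ac_pvalue(10, 0, 1e6, 1e6))
  add("exact_tests", "hypergeometric tail, k=2 n=3 K=4 N=10",
      1 / 3, hypergeom_tail(2, 3, 4, 10))
  add("exact_tests", "BH step-up on (0.01, 0.02, 0.03)",
      0.03, max(bh_fdr(c(0.01, 0.02, 0.03))),
      all(bh_fdr(c(0.01, 0.02, 0.03)) == 0.03))
  expr <- matrix(c(10, 4, 4, 4), 1, dimnames = list("g1",
                                                    c("MS", "MP", "MO", "SL")))
  add("exact_tests", "fold-only preferential (10 vs 4,4,4)", 1,
      as.numeric(identical(call_preferential_fold_only(expr, "MS"), "g1")))

  out <- do.call(rbind, rows)
  class(out) <- c("worked_examples", "data.frame")
  out
}
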
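test_that("sim_config validation names the offending field", {
  expect_error(sim_config(n_genes = -5), "n_genes")
  expect_error(sim_config(preferential_fold = 0.5), "preferential_fold")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(library_sizes = c(1e6, 1e6)), "library_sizes")
  expect_error(sim_config(n_genes = 100, n_specific = 60,
                          n_preferential = 60),
               "n_specific")
})

test_that("simulate_counts is deterministic under a fixed seed", {
  cf <- sim_config(n_genes = 300, n_specific = 10, n_preferential = 10,
                   seed = 7)
  a <- simulate_counts(cf)
  b <- simulate_counts(cf)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$lengths, b$lengths)
  expect_identical(a$truth, b$truth)
  # and it restores the caller's RNG state
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_counts(cf)); after <- runif(1)
  expect_identical(before, after)
})

test_that("truth labels match the configuration", {
  cf <- sim_config(n_genes = 1000, n_specific = 40, n_preferential = 30,
                   silent_fraction = 0.1, seed = 3)
  sim <- simulate_counts(cf)
  tab <- table(sim$truth$label)
  expect_equal(unname(tab[c("specific", "preferential", "silent")]),
               c(40, 30, 100), ignore_attr = TRUE)
  # specific genes have rate 0 outside the focal tissue (and so, under
  # Poisson sampling, exactly zero counts) and a floored focal rate
  spec <- sim$truth$gene_id[sim$truth$label == "specific"]
  expect_true(all(sim$counts$counts[spec, c("MP", "MO", "SL")] == 0))
  expect_true(all(sim$rates[spec, "MS"] >= cf$specific_min_cpm))
  # preferential genes carry the configured fold on the focal rate
  pref <- sim$truth$gene_id[sim$truth$label == "preferential"]
  expect_equal(sim$rates[pref, "MS"], sim$rates[pref, "MP"] * 8)
  # silent genes never produce reads in Poisson mode
  sil <- sim$truth$gene_id[sim$truth$label == "silent"]
  expect_true(all(sim$counts$counts[sil, ] == 0))
})

test_that("a null configuration is symmetric and exchangeable across tissues", {
  cf <- sim_config(n_genes = 3000, n_specific = 0, n_preferential = 0,
                   library_sizes = rep(5e6, 4), dispersion = 0, seed = 11)
  sim <- simulate_counts(cf)
  expect_true(all(sim$truth$label %in% c("background", "silent")))
  expect_identical(sim$rates[, 1], sim$rates[, 2])
  # sign test on count differences between two equal-depth libraries
  d <- sim$counts$counts[, "MS"] - sim$counts$counts[, "MP"]
  d <- d[d != 0]
  expect_gt(binom.test(sum(d > 0), length(d))$p.value, 0.01)
})

test_that("simulated counts match their configured means", {
  # aggregate count totals stay within 3 standard errors of expectation
  for (disp in c(0, 0.2)) {
    cf <- sim_config(n_genes = 10000, n_specific = 0, n_preferential = 0,
                     dispersion = disp, seed = 13 + disp)
    sim <- simulate_counts(cf)
    mu <- sweep(sim$rates, 2, cf$library_sizes / 1e6, "*")
    v <- mu + disp * mu^2
    for (t in colnames(mu)) {
      z <- (sum(sim$counts$counts[, t]) - sum(mu[, t])) / sqrt(sum(v[, t]))
      expect_lt(abs(z), 3)
    }
  }
})

test_that("calibrated column sums land close to the configured depths", {
  cf <- sim_config(n_genes = 5000, n_specific = 0, n_preferential = 0,
                   seed = 17)
  sim <- simulate_counts(cf)
  realized <- colSums(sim$counts$counts)
  expect_true(all(abs(realized - cf$library_sizes) / cf$library_sizes < 0.05))
  # downstream sees the realized totals, keeping normalization self-consistent
  expect_identical(sim$counts$library_sizes, realized)
})

test_that("simulate_hits validates its configuration", {
  expect_error(simulate_hits(c("a", "b"), c("x"), 2), "n_matched")
  expect_error(simulate_hits("a", "x", 1, e_range = c(1e-5, 1e-2)),
               "e_range")
  sim <- simulate_hits(sprintf("f%02d", 1:10), sprintf("o%02d", 1:15), 5,
                       seed = 5)
  again <- simulate_hits(sprintf("f%02d", 1:10), sprintf("o%02d", 1:15), 5,
                         seed = 5)
  expect_identical(sim$hits, again$hits)
  expect_true(all(sim$hits$evalue >= 0))
  # exactly n_matched focal genes carry a qualifying hit
  qualified <- unique(sim$hits$qseqid[sim$hits$evalue <= 1e-10])
  expect_length(qualified, 5)
})

test_that("simulate_annotation plants the requested enrichment", {
  genes <- sprintf("g%05d", 1:200)
  ann <- simulate_annotation(genes, n_terms = 4, planted_term = 3,
                             query_set = genes[1:80], enrichment_odds = 20,
                             base_rate = 0.1, seed = 19)
  expect_identical(ann$planted_term, "T003")
  again <- simulate_annotation(genes, n_terms = 4, planted_term = 3,
                               query_set = genes[1:80],
                               enrichment_odds = 20, base_rate = 0.1,
                               seed = 19)
  expect_identical(ann$table, again$table)
  # planted term is denser inside the query than outside
  set <- ann$annotation$sets[["T003"]]
  rate_in <- length(intersect(set, genes[1:80])) / 80
  rate_out <- length(setdiff(set, genes[1:80])) / 120
  expect_gt(rate_in, rate_out)
  expect_error(simulate_annotation(genes, 4, planted_term = 9,
                                   query_set = genes[1], seed = 1),
               "planted_term")
  expect_error(simulate_annotation(genes, 4, query_set = "not_a_gene",
                                   enrichment_odds = 2, seed = 1),
               "query_set")
})
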
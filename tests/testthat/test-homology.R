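hit_row <- function(q, s, e, pident = 80, bits = 100) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = 200,
             mismatch = 10, gapopen = 1, qstart = 1, qend = 200, sstart = 1,
             send = 200, evalue = e, bitscore = bits)
}

test_that("best_hits filters and selects the lowest-E subject", {
  hits <- rbind(hit_row("q1", "s1", 1e-12),
                hit_row("q2", "s1", 1e-12), hit_row("q2", "s2", 1e-20),
                hit_row("q3", "s1", 1e-9))
  bh <- best_hits(hits)
  expect_equal(bh$subject_id[bh$query_id == "q1"], "s1")
  expect_equal(bh$subject_id[bh$query_id == "q2"], "s2")
  expect_false("q3" %in% bh$query_id)        # 1e-9 fails e_max 1e-10
  # the boundary is inclusive in homolog mode, exclusive in strict mode
  expect_equal(best_hits(hit_row("q", "s", 1e-10))$query_id, "q")
  expect_equal(nrow(best_hits(hit_row("q", "s", 1e-20), e_max = 1e-20,
                              e_strict = TRUE)), 0)
})

test_that("best_hits breaks ties by bitscore then subject id", {
  hits <- rbind(hit_row("q1", "s2", 1e-15, bits = 120),
                hit_row("q1", "s1", 1e-15, bits = 90),
                hit_row("q2", "sB", 1e-15, bits = 100),
                hit_row("q2", "sA", 1e-15, bits = 100))
  bh <- best_hits(hits)
  expect_equal(bh$subject_id[bh$query_id == "q1"], "s2")
  expect_equal(bh$subject_id[bh$query_id == "q2"], "sA")
})

test_that("best_hits applies identity and subject filters", {
  hits <- rbind(hit_row("q1", "s1", 1e-25, pident = 75),
                hit_row("q1", "s2", 1e-22, pident = 90),
                hit_row("q2", "s3", 1e-25, pident = 90))
  bh <- best_hits(hits, e_max = 1e-20, e_strict = TRUE, min_identity = 80)
  expect_equal(bh$subject_id[bh$query_id == "q1"], "s2")
  # identity floor is strict
  expect_equal(nrow(best_hits(hit_row("q", "s", 1e-25, pident = 80),
                              min_identity = 80)), 0)
  bh2 <- best_hits(hits, subject_filter = c("s1", "s3"))
  expect_equal(sort(bh2$subject_id), c("s1", "s3"))
})

test_that("best_hits is idempotent on its own output", {
  set.seed(21)
  sim <- simulate_hits(sprintf("f%03d", 1:40), sprintf("o%03d", 1:40),
                       n_matched = 25, seed = 9)
  bh <- best_hits(sim$hits)
  again <- best_hits(data.frame(qseqid = bh$query_id, sseqid = bh$subject_id,
                                pident = bh$pident, evalue = bh$evalue,
                                bitscore = bh$bitscore))
  expect_equal(again, bh)
})

test_that("best_hits recovers the planted pairing from simulated hit tables", {
  sim <- simulate_hits(sprintf("f%03d", 1:60), sprintf("o%03d", 1:80),
                       n_matched = 35, seed = 4)
  bh <- best_hits(sim$hits)
  expect_setequal(bh$query_id, sim$truth$query_id)
  truth_map <- setNames(sim$truth$subject_id, sim$truth$query_id)
  expect_equal(setNames(bh$subject_id, bh$query_id)[names(truth_map)],
               truth_map)
  # n_matched = 0 gives an empty map; full single-hit matching is an identity
  empty <- simulate_hits(c("a", "b"), c("x", "y"), 0, seed = 1, n_decoys = 0)
  expect_equal(nrow(best_hits(empty$hits)), 0)
  full <- simulate_hits(sprintf("f%02d", 1:10), sprintf("o%02d", 1:10), 10,
                        seed = 2, extra_hit_prob = 0, n_decoys = 0)
  bh_full <- best_hits(full$hits)
  expect_setequal(bh_full$query_id, sprintf("f%02d", 1:10))
  expect_equal(setNames(bh_full$subject_id, bh_full$query_id),
               setNames(full$truth$subject_id, full$truth$query_id)[bh_full$query_id])
})

test_that("hit tables round-trip through TSV and malformed rows are located", {
  sim <- simulate_hits(sprintf("f%03d", 1:20), sprintf("o%03d", 1:20),
                       n_matched = 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(sim$hits, path)
  back <- read_hits(path)
  expect_equal(back$qseqid, sim$hits$qseqid)
  expect_equal(back$evalue, sim$hits$evalue, tolerance = 1e-6)

  lines <- readLines(path)
  lines[4] <- sub("^([^\t]*\t[^\t]*\t)[^\t]*", "\\1not_a_number", lines[4])
  writeLines(lines, path)
  expect_error(read_hits(path), "line 4")
})

test_that("conservation partition reproduces the published set arithmetic", {
  sets <- make_partition_sets(1427, 471, 140, 107,
                              n_subj_a = 213, n_subj_b = 37)
  part <- conservation_partition(sets$focal, sets$map_a, sets$map_b)
  expect_length(part$distinct, 923)
  expect_length(part$hit_a_only, 364)
  expect_length(part$hit_both, 107)
  expect_length(part$matched_a, 213)
  expect_length(part$matched_b, 37)

  summ <- partition_summary(part, size_a = 548, size_b = 115)
  expect_equal(summ$percent[summ$subset == "subjects_a"], 38.87)  # 213/548
  expect_equal(summ$percent[summ$subset == "hit_b"], 9.81)        # 140/1427
  expect_equal(summ$count[summ$subset == "hit_a"], 471)
})

test_that("partition subsets are disjoint, exhaustive, and obey inclusion-exclusion", {
  set.seed(31)
  for (i in 1:10) {
    focal <- sprintf("f%03d", 1:80)
    map_a <- setNames(sample(letters, 30, TRUE), sample(focal, 30))
    map_b <- setNames(sample(letters, 20, TRUE), sample(focal, 20))
    part <- conservation_partition(focal, map_a, map_b)
    parts <- list(part$hit_both, part$hit_a_only, part$hit_b_only,
                  part$distinct)
    expect_equal(sort(unlist(parts)), sort(focal))
    expect_equal(length(part$distinct),
                 80 - length(names(map_a)) - length(names(map_b)) +
                   length(intersect(names(map_a), names(map_b))))
  }
  empty <- setNames(character(), character())
  part0 <- conservation_partition(c("a", "b"), empty, empty)
  expect_equal(part0$distinct, c("a", "b"))
})

test_that("partition_summary validates denominators and reports zero matches", {
  sets <- make_partition_sets(10, 0, 0, 0)
  part <- conservation_partition(sets$focal, sets$map_a, sets$map_b)
  summ <- partition_summary(part, size_a = 5, size_b = 5)
  expect_equal(summ$percent[summ$subset == "subjects_a"], 0)
  expect_error(partition_summary(part, size_a = 0), "zero")
})
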
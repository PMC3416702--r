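test_that("count_table validates its inputs", {
  m <- matrix(c(10, 0, 5, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("MS", "MP")))
  ct <- count_table(m, c(MS = 1e6, MP = 2e6))
  expect_s3_class(ct, "count_table")
  expect_named(ct$library_sizes, c("MS", "MP"))

  expect_error(count_table(m, c(MS = 5, MP = 2e6)), "column sum")
  expect_error(count_table(m, c(1e6, 2e6, 3e6)), "one entry per tissue")
  expect_error(count_table(unname(m), c(1e6, 2e6)), "row names")
  m2 <- m; m2[1, 1] <- -1
  expect_error(count_table(m2, c(MS = 1e6, MP = 2e6)), "non-negative")
  expect_warning(count_table(m, c(MS = 1e6, MP = 2e6), warn_mismatch = TRUE),
                 ">1%")
})

test_that("longest_lengths keeps the maximum transcript length per gene", {
  tx <- data.frame(gene_id = c("g1", "g1", "g2", "g3", "g3"),
                   length = c(1200, 800, 500, 900, 900))
  out <- longest_lengths(tx)
  expect_equal(out[c("g1", "g2", "g3")], c(g1 = 1200, g2 = 500, g3 = 900))
  expect_error(
    longest_lengths(data.frame(gene_id = c("g1", "g2"), length = c(100, 0))),
    "g2")
})

test_that("gff3_lengths sums exon lengths and keeps the longest transcript", {
  gff <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t5000\t.\t+\t.\tID=gene:GA",
    "chr1\tsrc\tmRNA\t100\t3000\t.\t+\t.\tID=transcript:GA.1;Parent=gene:GA",
    "chr1\tsrc\texon\t100\t600\t.\t+\t.\tParent=transcript:GA.1",
    "chr1\tsrc\texon\t1000\t1499\t.\t+\t.\tParent=transcript:GA.1",
    "chr1\tsrc\tmRNA\t100\t5000\t.\t+\t.\tID=transcript:GA.2;Parent=gene:GA",
    "chr1\tsrc\texon\t100\t400\t.\t+\t.\tParent=transcript:GA.2",
    "chr1\tsrc\tgene\t8000\t9000\t.\t-\t.\tID=gene:GB",
    "chr1\tsrc\tmRNA\t8000\t9000\t.\t-\t.\tID=transcript:GB.1;Parent=gene:GB",
    "chr1\tsrc\texon\t8000\t8999\t.\t-\t.\tParent=transcript:GB.1")
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, path)
  out <- gff3_lengths(path)
  # GA.1: 501 + 500 = 1001 beats GA.2: 301; GB.1: 1000
  expect_equal(out[c("GA", "GB")], c(GA = 1001, GB = 1000))
})

test_that("rpkm matches its closed form and preserves zeros", {
  m <- matrix(c(10, 0, 50), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "MS"))
  ct <- count_table(m, c(MS = 1e6))
  out <- rpkm(ct, c(g1 = 1000, g2 = 800, g3 = 2500))
  expect_equal(out["g1", "MS"], 10)       # 1e9 * 10 / (1e6 * 1000)
  expect_equal(out["g2", "MS"], 0)
  ct2 <- count_table(m, c(MS = 2e6))
  expect_equal(rpkm(ct2, c(g1 = 1000, g2 = 800, g3 = 2500))["g3", "MS"], 10)

  expect_error(rpkm(ct, c(g1 = 1000, g2 = 800)), "g3")
})

test_that("rpkm is invariant under joint count/depth scaling", {
  ct <- rand_count_table(30)
  lens <- setNames(round(runif(30, 200, 5000)),
                   rownames(ct$counts))
  doubled <- count_table(ct$counts * 2, ct$library_sizes * 2)
  expect_equal(rpkm(doubled, lens), rpkm(ct, lens))
})

test_that("presence filter is inclusive at the per-million boundary", {
  m <- matrix(c(4, 3, 8), 3, 1, dimnames = list(c("g1", "g2", "g3"), "MS"))
  expect_equal(
    unname(call_expressed(count_table(m, c(MS = 1e6)))[, 1]),
    c(TRUE, FALSE, TRUE))
  # 8 reads in a 2M library is exactly 4 per million
  expect_true(call_expressed(count_table(m, c(MS = 2e6)))["g3", "MS"])
  expect_false(call_expressed(count_table(m, c(MS = 2e6)))["g1", "MS"])
})

test_that("presence calls are monotone in counts and antitone in depth", {
  n <- 200
  C <- rpois(n, 10)
  m1 <- matrix(C, n, 1, dimnames = list(sprintf("g%03d", 1:n), "MS"))
  m2 <- matrix(C + rpois(n, 5), n, 1, dimnames = dimnames(m1))
  e1 <- call_expressed(count_table(m1, c(MS = 2e6)))
  e2 <- call_expressed(count_table(m2, c(MS = 2e6)))
  expect_true(all(e2[e1]))  # more reads never turns a call off
  deeper <- call_expressed(count_table(m1, c(MS = 4e6)))
  expect_true(all(e1[deeper]))  # larger library never turns a call on
})

test_that("venn partition matches brute-force enumeration", {
  for (i in 1:10) {
    calls <- rand_calls(30, p = runif(1, 0.2, 0.8))
    got <- venn_partition(calls)
    want <- oracle_venn(calls)
    expect_equal(got[names(want)], want)
    expect_equal(sum(got), sum(rowSums(calls) > 0))
  }
})

test_that("venn partition handles degenerate patterns", {
  calls <- matrix(TRUE, 3, 4,
                  dimnames = list(c("g1", "g2", "g3"),
                                  c("MS", "MP", "MO", "SL")))
  out <- venn_partition(calls)
  expect_equal(out[["MS&MP&MO&SL"]], 3)
  expect_equal(sum(out), 3)
  expect_equal(sum(venn_partition(calls & FALSE)), 0)
})

test_that("specific calls are exclusive to the focal tissue", {
  calls <- rbind(g1 = c(TRUE, FALSE, FALSE, FALSE),
                 g2 = c(TRUE, FALSE, TRUE, FALSE),
                 g3 = c(FALSE, TRUE, FALSE, FALSE))
  colnames(calls) <- c("MS", "MP", "MO", "SL")
  expect_equal(call_specific(calls, "MS"), "g1")
  expect_equal(call_specific(calls, "MP"), "g3")
  expect_error(call_specific(calls, "XX"), "unknown tissue")
})

test_that("specific sets for different tissues are disjoint", {
  for (i in 1:5) {
    calls <- rand_calls(60)
    sets <- lapply(colnames(calls), call_specific, calls = calls)
    all_pairs <- combn(length(sets), 2)
    for (j in seq_len(ncol(all_pairs)))
      expect_length(
        intersect(sets[[all_pairs[1, j]]], sets[[all_pairs[2, j]]]), 0)
  }
})
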
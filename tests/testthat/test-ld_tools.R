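test_that("r2 is squared Pearson correlation of dosages", {
  panel <- cbind(s1 = c(0, 1, 2, 1), s2 = c(0, 1, 1, 2),
                 s3 = c(0, 1, 2, 1))
  ld <- compute_r2(panel)
  expect_equal(ld[ld$snp_a == "s1" & ld$snp_b == "s2"]$r2, 0.25)
  expect_equal(ld[ld$snp_a == "s1" & ld$snp_b == "s3"]$r2, 1)
  expect_error(compute_r2(panel[1, , drop = FALSE]), "individuals")
})

test_that("zero-variance columns are skipped with a warning", {
  panel <- cbind(s1 = c(0, 1, 2), s2 = c(1, 1, 1), s3 = c(2, 1, 0))
  expect_warning(ld <- compute_r2(panel), "zero-variance")
  expect_false("s2" %in% c(ld$snp_a, ld$snp_b))
})

test_that("computed r2 matches brute-force correlation on random panels", {
  set.seed(42)
  for (rep in 1:5) {
    panel <- matrix(runif(30 * 20, 0, 2), nrow = 30,
                    dimnames = list(NULL, sprintf("v%02d", 1:20)))
    ld <- compute_r2(panel)
    for (k in sample(nrow(ld), 10)) {
      expect_equal(ld$r2[k],
                   cor(panel[, ld$snp_a[k]], panel[, ld$snp_b[k]])^2,
                   tolerance = 1e-12)
    }
  }
})

test_that("pruning drops the smaller-MAF member and leaves no high-LD pair", {
  snps <- data.frame(snp_id = c("A", "B", "C"), maf = c(0.3, 0.1, 0.4))
  ld <- data.table::data.table(snp_a = c("A", "A", "B"),
                               snp_b = c("B", "C", "C"),
                               r2 = c(0.5, 0.25, 0.1))
  res <- prune_ld(snps, ld, r2_threshold = 0.2)
  expect_equal(res$kept, "C")
  expect_setequal(res$removed$snp_id, c("A", "B"))
  expect_equal(res$removed[snp_id == "B"]$vs, "A")
  expect_equal(res$removed[snp_id == "A"]$vs, "C")
})

test_that("pruning is a no-op below threshold and errors on bad input", {
  snps <- data.frame(snp_id = c("A", "B"), maf = c(0.3, 0.1))
  ld <- data.table::data.table(snp_a = "A", snp_b = "B", r2 = 0.15)
  res <- prune_ld(snps, ld, 0.2)
  expect_equal(res$kept, c("A", "B"))
  expect_equal(nrow(res$removed), 0L)
  expect_error(prune_ld(snps, ld, -1), "nonnegative")
  expect_error(
    prune_ld(snps, data.table::data.table(snp_a = "A", snp_b = "Z",
                                          r2 = 0.9), 0.2),
    "absent")
})

test_that("equal-MAF ties drop the lexicographically larger id", {
  snps <- data.frame(snp_id = c("A", "B"), maf = c(0.2, 0.2))
  ld <- data.table::data.table(snp_a = "A", snp_b = "B", r2 = 0.9)
  res <- prune_ld(snps, ld, 0.2)
  expect_equal(res$kept, "A")
  expect_equal(res$removed$snp_id, "B")
})

test_that("pruned sets are edge-free and pruning is idempotent (fuzzed)", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    ids <- sprintf("v%02d", seq_len(n))
    snps <- data.frame(snp_id = ids, maf = round(runif(n, 0.01, 0.5), 2),
                       chrom = "1", pos = seq_len(n) * 50L)
    npairs <- sample(5:60, 1)
    ld <- canonical_ld_pairs(data.table::data.table(
      snp_a = sample(ids, npairs, replace = TRUE),
      snp_b = sample(ids, npairs, replace = TRUE),
      r2 = runif(npairs)))
    res <- prune_ld(snps, ld, 0.2)
    expect_setequal(c(res$kept, res$removed$snp_id), ids)
    # exhaustive scan: no surviving pair above threshold
    bad <- ld[ld$r2 > 0.2 & ld$snp_a %in% res$kept & ld$snp_b %in% res$kept]
    expect_equal(nrow(bad), 0L)
    # idempotence
    res2 <- prune_ld(snps[snps$snp_id %in% res$kept, ],
                     ld[ld$snp_a %in% res$kept & ld$snp_b %in% res$kept],
                     0.2)
    expect_equal(nrow(res2$removed), 0L)
  }
})

test_that("max_r2_to_set handles membership, maxima and absent pairs", {
  ld <- canonical_ld_pairs(data.table::data.table(
    snp_a = c("q", "q"), snp_b = c("x", "y"), r2 = c(0.5, 0.9)))
  expect_equal(max_r2_to_set("x", c("x", "y"), ld), 1)
  expect_equal(max_r2_to_set("q", c("x", "y"), ld), 0.9)
  expect_equal(max_r2_to_set("z", c("x", "y"), ld), 0)
})

test_that("ld pair tables round-trip through the PLINK-style format", {
  ld <- canonical_ld_pairs(data.table::data.table(
    snp_a = c("b", "a"), snp_b = c("a", "c"), r2 = c(0.5, 0.1)))
  f <- withr::local_tempfile(fileext = ".ld")
  write_ld_pairs(ld, f)
  back <- read_ld_pairs(f)
  expect_equal(back$snp_a, ld$snp_a)
  expect_equal(back$r2, ld$r2)
})
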
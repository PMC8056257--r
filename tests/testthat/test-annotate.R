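make_catalog <- function(ids) {
  data.table::data.table(snp_id = ids, chrom = "1",
                         pos = seq_along(ids) * 1000L)
}

test_that("novelty status follows catalog membership and LD blocks", {
  ld <- canonical_ld_pairs(data.table::data.table(
    snp_a = c("s2", "s3"), snp_b = c("k1", "k1"), r2 = c(0.9, 0.5)))
  cat <- make_catalog(c("k1", "k2"))
  nov <- classify_novelty(c("k1", "s2", "s3", "s4"), cat, ld)
  expect_equal(nov$status,
               c("replicate-direct", "replicate-ld", "novel", "novel"))
  expect_equal(nov$best_r2, c(1, 0.9, 0.5, 0))
  expect_equal(nov$best_catalog_match[1:3], c("k1", "k1", "k1"))
  expect_true(is.na(nov$best_catalog_match[4]))
  cnt <- attr(nov, "counts")
  expect_equal(sum(cnt), 4L)
})

test_that("every significant SNP gets exactly one status; counts add up", {
  set.seed(31)
  ids <- sprintf("s%03d", 1:40)
  cat <- make_catalog(sample(ids, 5))
  pr <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  pr <- pr[pr$a < pr$b, ]
  pr <- pr[sample(nrow(pr), 100), ]
  ld <- canonical_ld_pairs(data.table::data.table(
    snp_a = pr$a, snp_b = pr$b, r2 = runif(100)))
  nov <- classify_novelty(ids, cat, ld)
  expect_equal(nrow(nov), 40L)
  expect_equal(sum(attr(nov, "counts")), 40L)
  expect_true(all(nov$status[nov$best_r2 >= 0.8] != "novel"))
  expect_true(all(nov$best_r2[nov$status == "novel"] < 0.8))
})

test_that("raising the block threshold never converts novel to replicate", {
  set.seed(32)
  ids <- sprintf("s%03d", 1:30)
  cat <- make_catalog(ids[1:4])
  ld <- canonical_ld_pairs(data.table::data.table(
    snp_a = sample(ids, 60, TRUE), snp_b = sample(ids, 60, TRUE),
    r2 = runif(60)))
  lo <- classify_novelty(ids, cat, ld, block_r2 = 0.5)
  hi <- classify_novelty(ids, cat, ld, block_r2 = 0.9)
  novel_lo <- lo$snp_id[lo$status == "novel"]
  novel_hi <- hi$snp_id[hi$status == "novel"]
  expect_true(all(novel_lo %in% novel_hi))
})

test_that("empty significant set yields an empty result, not an error", {
  nov <- classify_novelty(character(), make_catalog("k1"),
                          empty_ld_pairs_for_test())
  expect_equal(nrow(nov), 0L)
})

test_that("gene mapping honors body, flank and joint labels", {
  genes <- data.frame(gene = c("GENEA", "GENEB"), chrom = "1",
                      start = c(1000L, 4500L), end = c(5000L, 9000L))
  snps <- data.frame(snp_id = c("in_a", "up_a", "overlap", "far"),
                     chrom = "1",
                     pos = c(2000L, 995000L, 4800L, 500000L))
  snps$pos[2] <- 995L  # 5 bp upstream of GENEA
  ga <- map_genes(snps, genes, flank_bp = 10L)
  expect_equal(ga$label[1], "GENEA")
  expect_equal(ga$relations[[1]], "within")
  expect_equal(ga$label[2], "GENEA")
  expect_equal(ga$relations[[2]], "near")
  expect_equal(ga$label[3], "GENEA/GENEB")
  expect_equal(ga$label[4], "")
  expect_equal(attr(ga, "unmapped"), "far")
  bad <- data.frame(gene = "X", chrom = "1", start = 10L, end = 5L)
  expect_error(map_genes(snps, bad), "X")
})

test_that("BED intervals convert to 1-based inclusive coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t5000\tGENEA", "1\t4499\t9000\tGENEB"), f)
  genes <- read_gene_bed(f)
  expect_equal(genes$start, c(1000L, 4500L))
  expect_equal(genes$end, c(5000L, 9000L))
  expect_equal(genes$chrom, c("1", "1"))
  # a SNP at the BED start coordinate (0-based) is NOT inside; at start+1 it is
  ga <- map_genes(data.frame(snp_id = c("x", "y"), chrom = "1",
                             pos = c(999L, 1000L)), genes, flank_bp = 0L)
  expect_equal(ga$label, c("", "GENEA"))
})
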
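test_that("config validation rejects inconsistent mixtures", {
  expect_error(sim_config(pi = c(0.9, 0.05, 0.05, 0.05)), "sum to 1")
  expect_error(sim_config(pi = c(1.1, -0.1, 0, 0)), "nonnegative")
  expect_error(sim_config(sigma = 0), "sigma")
})

test_that("the same seed reproduces every artifact bit-for-bit", {
  cfg <- sim_config(n_snps = 2000, seed = 77)
  s1 <- simulate_joint_gwas(cfg)
  s2 <- simulate_joint_gwas(cfg)
  expect_identical(s1, s2)
  l1 <- simulate_ld_panel(s1$trait1[1:60, ], cfg)
  l2 <- simulate_ld_panel(s1$trait1[1:60, ], cfg)
  expect_identical(l1, l2)
  e1 <- simulate_expression(c("A", "B"), seed = 5)
  e2 <- simulate_expression(c("A", "B"), seed = 5)
  expect_identical(e1, e2)
  e3 <- simulate_expression(c("A", "B"), seed = 6)
  expect_false(identical(e1$expr, e3$expr))
})

test_that("p-values are valid and null p-values are uniform", {
  cfg <- sim_config(n_snps = 20000, pi = c(1, 0, 0, 0), seed = 8)
  sim <- simulate_joint_gwas(cfg)
  p <- sim$trait1$p_value
  expect_true(all(p > 0 & p <= 1))
  expect_true(all(sim$truth$component == "00"))
  # fraction below 0.05 within Monte-Carlo error (SE ~ 0.0015)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.006)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("without pleiotropy the two traits' z-scores are uncorrelated", {
  cfg <- sim_config(n_snps = 50000, pi = c(0.96, 0.02, 0.02, 0),
                    seed = 9)
  sim <- simulate_joint_gwas(cfg)
  expect_lt(abs(cor(sim$truth$z1, sim$truth$z2)), 0.015)
})

test_that("component frequencies follow the configured fractions", {
  cfg <- sim_config(n_snps = 50000, seed = 10)
  sim <- simulate_joint_gwas(cfg)
  freq <- table(factor(sim$truth$component,
                       levels = c("00", "10", "01", "11"))) / 50000
  expect_equal(as.numeric(freq), c(0.94, 0.02, 0.02, 0.02),
               tolerance = 0.15)
  # pleiotropic effect means correlate at rho
  i11 <- sim$truth$component == "11"
  expect_equal(cor(sim$truth$mu1[i11], sim$truth$mu2[i11]), 0.8,
               tolerance = 0.05)
})

test_that("LD panel realizes the target within-block r2", {
  cfg <- sim_config(n_snps = 200, block_size = 5L, block_r2 = 0.9,
                    n_individuals = 200L, seed = 11)
  sim <- simulate_joint_gwas(cfg)
  ld <- simulate_ld_panel(sim$trait1, cfg)
  expect_true(all(ld$panel >= 0 & ld$panel <= 2))
  expect_gt(mean(ld$pairs$r2), 0.8)
  expect_lte(max(ld$pairs$r2), 1)
  # across-block independence: compute r2 across the whole panel and
  # compare the cross-block pairs to the null baseline
  all_pairs <- compute_r2(ld$panel)
  blk <- ld$blocks[match(all_pairs$snp_a, colnames(ld$panel))] ==
    ld$blocks[match(all_pairs$snp_b, colnames(ld$panel))]
  expect_lt(mean(all_pairs$r2[!blk]), 0.03)  # E[r2] under null ~ 1/n_ind
})

test_that("singleton blocks generate no pairs", {
  cfg <- sim_config(n_snps = 10, block_size = 1L, seed = 12)
  sim <- simulate_joint_gwas(cfg)
  ld <- simulate_ld_panel(sim$trait1, cfg)
  expect_equal(nrow(ld$pairs), 0L)
  expect_error(
    simulate_ld_panel(sim$trait1,
                      sim_config(n_snps = 10, block_size = 50L, seed = 1)),
    "block size")
})

test_that("expression effects shift groups and couple to the trait", {
  genes <- sprintf("G%02d", 1:40)
  sim <- simulate_expression(genes, n_group = c(16L, 12L),
                             effect_genes = "G01", effect_size = 2,
                             seed = 13)
  expect_equal(dim(sim$expr), c(40L, 28L))
  expect_equal(nrow(sim$meta), 28L)
  p_eff <- rank_sum_test(sim$expr["G01", sim$meta$group == "group1"],
                         sim$expr["G01", sim$meta$group == "group2"])$p_value
  expect_lt(p_eff, 0.05)
  expect_error(simulate_expression(genes, effect_genes = "nope"), "subset")
  expect_error(simulate_expression(genes, n_group = c(0L, 5L)), "n_group")
})

test_that("simulation artifacts round-trip through the pipeline formats", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_snps = 300, seed = 14)
  sim <- simulate_joint_gwas(cfg)
  ld <- simulate_ld_panel(sim$trait1, cfg)
  catalog <- data.table::data.table(snp_id = sim$trait1$snp_id[1:5],
                                    chrom = sim$trait1$chrom[1:5],
                                    pos = sim$trait1$pos[1:5])
  write_simulation(sim, dir, ld = ld, catalog = catalog)
  t1 <- read_summary_stats(file.path(dir, "trait1.tsv"))
  expect_equal(nrow(t1), 300L)
  expect_equal(t1$p_value, sim$trait1$p_value)
  back <- read_ld_pairs(file.path(dir, "ld.tsv"))
  expect_equal(nrow(back), nrow(ld$pairs))
  cat_back <- read_catalog(file.path(dir, "catalog.tsv"))
  expect_equal(cat_back$snp_id, catalog$snp_id)
})
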
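#' Configuration for the two-trait synthetic GWAS generator
#'
#' The generative model works at the z-score level, which is the natural
#' scale for a method that consumes only p-values. Each SNP belongs to one
#' of four latent components — null for both traits (`00`), specific to
#' trait 1 (`10`) or trait 2 (`01`), or pleiotropic (`11`) — drawn with the
#' configured fractions. For each trait the observed z is `mu + e` with
#' `e ~ N(0,1)`; `mu = 0` when the SNP is null for that trait and
#' `mu ~ N(0, sigma^2)` otherwise. For pleiotropic SNPs the two means are
#' drawn jointly with correlation `rho`, so `rho > 0` means shared-direction
#' effects dominate (negative `rho` models opposite-direction pleiotropy).
#'
#' @param n_snps Number of SNPs.
#' @param pi Mixture fractions `c(null, trait1, trait2, pleiotropic)`;
#'   must be nonnegative and sum to 1 (tolerance 1e-9). Default
#'   `c(0.94, 0.02, 0.02, 0.02)`.
#' @param sigma Standard deviation of non-null z-score means (> 0);
#'   default 3, a realistic polygenic effect scale for a well-powered scan.
#' @param rho Effect correlation for pleiotropic SNPs, in \[-1, 1\];
#'   default 0.8.
#' @param maf_range Uniform range for minor allele frequency, default
#'   `c(0.01, 0.5)`.
#' @param block_size SNPs per LD block in [simulate_ld_panel()]; a single
#'   number or a `c(min, max)` range sampled per block. Default 5.
#' @param block_r2 Target within-block r2 level, default 0.9.
#' @param n_individuals Panel depth for [simulate_ld_panel()], default 200.
#' @param n_chrom Chromosomes the SNPs are spread over, default 22.
#' @param seed Integer seed; fixes all outputs bit-for-bit. Stage-specific
#'   sub-seeds are derived deterministically from it.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 10000L,
                       pi = c(0.94, 0.02, 0.02, 0.02),
                       sigma = 3, rho = 0.8,
                       maf_range = c(0.01, 0.5),
                       block_size = 5L, block_r2 = 0.9,
                       n_individuals = 200L, n_chrom = 22L,
                       seed = 1L) {
  stopifnot(n_snps >= 1L, length(pi) == 4L)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("mixture fractions must be nonnegative and sum to 1")
  stopifnot(sigma > 0, rho >= -1, rho <= 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            n_individuals >= 2L)
  structure(list(n_snps = as.integer(n_snps), pi = pi, sigma = sigma,
                 rho = rho, maf_range = maf_range,
                 block_size = as.integer(block_size),
                 block_r2 = block_r2,
                 n_individuals = as.integer(n_individuals),
                 n_chrom = as.integer(n_chrom),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic sub-seed per stage, kept inside 32-bit integer range
sub_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage * 7919L
}

#' Simulate paired GWAS summary statistics with known truth
#'
#' Draws the four-component mixture of [sim_config()] and emits two
#' complete summary-statistics tables sharing SNP ids (the same schema
#' [read_summary_stats()] returns) plus the latent truth. Two-sided
#' p-values are `2 * pnorm(-|z|)`, so they are uniform for null SNPs and
#' never exactly 0; the reported beta is the z-score itself (its sign
#' defines the direction code). SNPs are laid out round-robin over
#' `n_chrom` chromosomes with 10 kb spacing.
#'
#' @param config A [sim_config()].
#' @return List with `trait1`, `trait2` (summary tables), `truth`
#'   (`data.table`: `snp_id`, `component` in `{"00","10","01","11"}`,
#'   `mu1`, `mu2`, `z1`, `z2`).
#' @export
simulate_joint_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  n <- config$n_snps
  comp <- sample(c("00", "10", "01", "11"), n, replace = TRUE,
                 prob = config$pi)
  mu1 <- numeric(n); mu2 <- numeric(n)
  i10 <- comp == "10"; i01 <- comp == "01"; i11 <- comp == "11"
  mu1[i10] <- stats::rnorm(sum(i10), 0, config$sigma)
  mu2[i01] <- stats::rnorm(sum(i01), 0, config$sigma)
  if (any(i11)) {
    k <- sum(i11)
    a <- stats::rnorm(k); b <- stats::rnorm(k)
    mu1[i11] <- config$sigma * a
    mu2[i11] <- config$sigma * (config$rho * a + sqrt(1 - config$rho^2) * b)
  }
  z1 <- mu1 + stats::rnorm(n)
  z2 <- mu2 + stats::rnorm(n)
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  snp_id <- sprintf("rs%07d", seq_len(n))
  chrom <- as.character(rep_len(seq_len(config$n_chrom), n))
  pos <- 10000L * (seq_len(n) %/% config$n_chrom + 1L)
  mk <- function(z, trait) {
    tab <- data.table::data.table(snp_id = snp_id, chrom = chrom, pos = pos,
                                  beta = z,
                                  p_value = 2 * stats::pnorm(-abs(z)),
                                  maf = maf)
    data.table::setattr(tab, "trait_name", trait)
    tab
  }
  list(trait1 = mk(z1, "trait1"), trait2 = mk(z2, "trait2"),
       truth = data.table::data.table(snp_id = snp_id, component = comp,
                                      mu1 = mu1, mu2 = mu2, z1 = z1, z2 = z2))
}

#' Simulate an LD reference panel with block structure
#'
#' Partitions the SNPs into consecutive blocks and generates continuous
#' dosages in \[0, 2\] from a per-block latent factor: within a block each
#' SNP loads on the shared factor with weight `sqrt(block_r2)`, so the
#' expected pairwise within-block r2 equals `block_r2`; across blocks SNPs
#' are independent. The realized pair set is computed from the panel with
#' [compute_r2()] and returned alongside it.
#'
#' @param snps `data.frame` with `snp_id` (order defines block layout).
#' @param config A [sim_config()] (`block_size`, `block_r2`,
#'   `n_individuals`, `seed` are used).
#' @return List with `panel` (individuals x SNPs numeric matrix),
#'   `pairs` (`ld_pairs` of realized within-block r2; across-block pairs
#'   are omitted as independent by construction), and `blocks` (integer
#'   block id per SNP).
#' @export
simulate_ld_panel <- function(snps, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 2L))
  ids <- snps$snp_id
  n <- length(ids)
  bs <- config$block_size
  if (length(bs) == 1L) bs <- c(bs, bs)
  if (bs[2] > n) stop("block size exceeds number of SNPs")
  blocks <- integer(n)
  b <- 0L; i <- 1L
  while (i <= n) {
    b <- b + 1L
    len <- if (bs[1] == bs[2]) bs[1] else
      sample(seq(bs[1], bs[2]), 1L)
    blocks[i:min(n, i + len - 1L)] <- b
    i <- i + len
  }
  m <- config$n_individuals
  load <- sqrt(sqrt(config$block_r2))   # per-SNP loading; pair corr = load^2
  panel <- matrix(0, nrow = m, ncol = n, dimnames = list(NULL, ids))
  for (blk in seq_len(b)) {
    cols <- which(blocks == blk)
    u <- stats::rnorm(m)
    for (j in cols) {
      raw <- load * u + sqrt(1 - load^2) * stats::rnorm(m)
      panel[, j] <- pmin(2, pmax(0, 1 + 0.4 * raw))
    }
  }
  pair_list <- vector("list", b)
  for (blk in seq_len(b)) {
    cols <- which(blocks == blk)
    if (length(cols) < 2L) next
    pair_list[[blk]] <- compute_r2(panel[, cols, drop = FALSE])
  }
  pairs <- data.table::rbindlist(pair_list)
  if (nrow(pairs) == 0L) pairs <- empty_ld_pairs("computed")
  else pairs <- canonical_ld_pairs(pairs, source = "computed")
  list(panel = panel, pairs = pairs, blocks = blocks)
}

#' Simulate an expression matrix with group and trait effects
#'
#' Baseline log-scale expression is standard normal per gene and sample.
#' Effect genes are shifted by `effect_size` (in baseline SD units) in the
#' second group, and/or linearly coupled to a continuous per-sample trait
#' with slope `trait_effect`. Emulates a two-group biopsy design (e.g. 16
#' young vs 12 old) with an optional continuous phenotype.
#'
#' @param genes Character vector of gene symbols.
#' @param n_group Integer vector `c(n1, n2)` of group sizes (default
#'   `c(16, 12)`); both >= 1.
#' @param effect_genes Subset of `genes` carrying the effect.
#' @param effect_size Group-2 mean shift in SD units (default 0).
#' @param trait_effect Linear coupling of effect genes to the trait
#'   (default 0 = no trait structure).
#' @param seed Integer seed.
#' @return List with `expr` (genes x samples matrix) and `meta`
#'   (`data.table`: `sample`, `group`, `trait`).
#' @export
simulate_expression <- function(genes, n_group = c(16L, 12L),
                                effect_genes = character(),
                                effect_size = 0, trait_effect = 0,
                                seed = 1L) {
  stopifnot(all(n_group >= 1L), length(n_group) == 2L)
  if (!all(effect_genes %in% genes))
    stop("effect_genes must be a subset of genes")
  set.seed(sub_seed(seed, 3L))
  n_s <- sum(n_group)
  group <- rep(c("group1", "group2"), n_group)
  trait <- stats::rnorm(n_s)
  expr <- matrix(stats::rnorm(length(genes) * n_s), nrow = length(genes),
                 dimnames = list(genes,
                                 sprintf("S%03d", seq_len(n_s))))
  if (length(effect_genes) > 0L) {
    expr[effect_genes, group == "group2"] <-
      expr[effect_genes, group == "group2"] + effect_size
    if (trait_effect != 0)
      expr[effect_genes, ] <- expr[effect_genes, ] +
        trait_effect * matrix(trait, nrow = length(effect_genes),
                              ncol = n_s, byrow = TRUE)
  }
  meta <- data.table::data.table(sample = colnames(expr), group = group,
                                 trait = trait)
  list(expr = expr, meta = meta)
}

#' Write every synthetic artifact to a directory
#'
#' Emits the same file formats the pipeline reads: `trait1.tsv` /
#' `trait2.tsv` summary tables, `panel.tsv` dosages, `ld.tsv` pair table,
#' `catalog.tsv`, `truth.tsv`.
#'
#' @param sim Output of [simulate_joint_gwas()].
#' @param dir Output directory (created if needed).
#' @param ld Optional output of [simulate_ld_panel()].
#' @param catalog Optional catalog `data.table` (see [read_catalog()]).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, ld = NULL, catalog = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_stats(sim$trait1, file.path(dir, "trait1.tsv"))
  write_summary_stats(sim$trait2, file.path(dir, "trait2.tsv"))
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  if (!is.null(ld)) {
    panel <- data.table::as.data.table(ld$panel)
    data.table::fwrite(panel, file.path(dir, "panel.tsv"), sep = "\t")
    write_ld_pairs(ld$pairs, file.path(dir, "ld.tsv"))
  }
  if (!is.null(catalog)) {
    data.table::fwrite(
      data.table::data.table(SNP = catalog$snp_id, CHR = catalog$chrom,
                             BP = catalog$pos),
      file.path(dir, "catalog.tsv"), sep = "\t")
  }
  invisible(dir)
}
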
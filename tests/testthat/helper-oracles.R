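# Independent brute-force oracles, deliberately naive: they share no code
# with the implementation paths they check.

# O(N^2) counting form of the conditional FDR estimator
brute_cfdr <- function(p, q) {
  n <- length(p)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- sum(q <= q[i])
    den <- sum(p <= p[i] & q <= q[i])
    out[i] <- min(1, p[i] * num / den)
  }
  out
}

# exact two-sided rank-sum p by full enumeration of group-A rank subsets
brute_ranksum_p <- function(a, b) {
  x <- c(a, b)
  stopifnot(!anyDuplicated(x))
  r <- rank(x)
  w_obs <- sum(r[seq_along(a)])
  combos <- utils::combn(length(x), length(a))
  ws <- apply(combos, 2L, function(ix) sum(rank(x)[ix]))
  mu <- length(a) * (length(x) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

empty_ld_pairs_for_test <- function() {
  data.table::data.table(snp_a = character(), snp_b = character(),
                         r2 = numeric())
}

# tiny merged table builder
merged_tab <- function(p1, p2) {
  n <- length(p1)
  data.table::data.table(
    snp_id = sprintf("s%03d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 100L,
    p1 = p1, p2 = p2,
    dir1 = "+", dir2 = "+", maf = 0.25)
}

# write a minimal summary-stats file
write_sumstats_file <- function(path, df,
                                header = c("SNP", "CHR", "BP", "BETA",
                                           "P", "MAF")) {
  names(df) <- header
  data.table::fwrite(df, path, sep = "\t")
  path
}
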
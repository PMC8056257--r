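#' Pairwise r-squared from a dosage panel
#'
#' LD between two markers is measured as the squared Pearson correlation of
#' their genotype dosage vectors across individuals (composite LD; phase is
#' not used). Zero-variance columns cannot be correlated and are skipped with
#' a warning.
#'
#' @param panel Numeric matrix of allele dosages, individuals x SNPs, values
#'   in \[0, 2\], with SNP ids as column names. A `data.frame` is accepted.
#' @param positions Optional named vector of base positions (names = SNP
#'   ids); required when `window_bp` is finite.
#' @param window_bp Restrict to pairs within this many base pairs on the same
#'   chromosome ordering (`Inf` = all pairs). Windowing bounds cost on large
#'   panels without changing results for nearby pairs.
#' @param chrom Optional named vector of chromosome labels per SNP; pairs on
#'   different chromosomes are skipped when supplied together with
#'   `positions`.
#' @return A `data.table` of class `ld_pairs` with columns `snp_a`, `snp_b`
#'   (`snp_a < snp_b` lexicographically), `r2`. Attribute `source` is
#'   `"computed"`.
#' @export
compute_r2 <- function(panel, positions = NULL, window_bp = Inf,
                       chrom = NULL) {
  m <- as.matrix(panel)
  if (nrow(m) < 2L) stop("at least 2 individuals required to compute LD")
  if (is.null(colnames(m))) stop("panel must carry SNP ids as column names")
  v <- apply(m, 2L, stats::var)
  if (any(v == 0)) {
    warning("skipping ", sum(v == 0), " zero-variance SNP column(s): ",
            paste(utils::head(colnames(m)[v == 0], 5L), collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  ids <- colnames(m)
  if (ncol(m) < 2L) {
    return(empty_ld_pairs("computed"))
  }
  cc <- stats::cor(m)
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  pairs <- data.table::data.table(
    snp_a = ids[ut[, 1L]], snp_b = ids[ut[, 2L]],
    r2 = cc[ut]^2)
  if (is.finite(window_bp)) {
    if (is.null(positions)) stop("positions required for windowed LD")
    pa <- positions[pairs$snp_a]; pb <- positions[pairs$snp_b]
    keep <- abs(pa - pb) <= window_bp
    if (!is.null(chrom)) keep <- keep & chrom[pairs$snp_a] == chrom[pairs$snp_b]
    pairs <- pairs[keep]
  }
  # clamp tiny floating overshoot
  pairs[, r2 := pmin(pmax(r2, 0), 1)]
  canonical_ld_pairs(pairs, source = "computed")
}

empty_ld_pairs <- function(source) {
  out <- data.table::data.table(snp_a = character(), snp_b = character(),
                                r2 = numeric())
  data.table::setattr(out, "source", source)
  data.table::setattr(out, "class", c("ld_pairs", class(out)))
  out
}

canonical_ld_pairs <- function(pairs, source = "file") {
  out <- data.table::data.table(
    snp_a = pmin(pairs$snp_a, pairs$snp_b),
    snp_b = pmax(pairs$snp_a, pairs$snp_b),
    r2 = pairs$r2)
  out <- out[snp_a != snp_b]
  out <- unique(out, by = c("snp_a", "snp_b"))
  data.table::setorder(out, snp_a, snp_b)
  data.table::setattr(out, "source", source)
  data.table::setattr(out, "class", c("ld_pairs", class(out)))
  out
}

#' Read / write PLINK-style `.ld` pair tables
#'
#' Layout: whitespace-delimited with header `CHR_A BP_A SNP_A CHR_B BP_B
#' SNP_B R2`. Only `SNP_A`, `SNP_B`, `R2` are required on read; the
#' positional columns are written as 0 when unknown.
#'
#' @param path File path.
#' @return `read_ld_pairs`: an `ld_pairs` table (see [compute_r2()]).
#' @export
read_ld_pairs <- function(path) {
  if (!file.exists(path)) stop("LD pair file not found: ", path)
  raw <- data.table::fread(path, header = TRUE)
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(raw)))
    stop("LD pair file must contain columns SNP_A, SNP_B, R2")
  out <- data.table::data.table(snp_a = as.character(raw$SNP_A),
                                snp_b = as.character(raw$SNP_B),
                                r2 = as.numeric(raw$R2))
  if (any(out$r2 < 0 | out$r2 > 1, na.rm = TRUE))
    stop("r2 values outside [0,1] in ", path)
  canonical_ld_pairs(out, source = "file")
}

#' @rdname read_ld_pairs
#' @param pairs An `ld_pairs` table.
#' @param meta Optional `data.frame` with `snp_id`, `chrom`, `pos` used to
#'   fill the positional columns.
#' @export
write_ld_pairs <- function(pairs, path, meta = NULL) {
  chr_of <- pos_of <- function(id) rep(0L, length(id))
  if (!is.null(meta)) {
    chr_of <- function(id) meta$chrom[match(id, meta$snp_id)]
    pos_of <- function(id) meta$pos[match(id, meta$snp_id)]
  }
  out <- data.table::data.table(
    CHR_A = chr_of(pairs$snp_a), BP_A = pos_of(pairs$snp_a),
    SNP_A = pairs$snp_a,
    CHR_B = chr_of(pairs$snp_b), BP_B = pos_of(pairs$snp_b),
    SNP_B = pairs$snp_b, R2 = pairs$r2)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Greedy MAF-aware LD pruning
#'
#' Removes one member of every SNP pair in high LD so that no pair with
#' `r2 > r2_threshold` survives: for each offending pair, the SNP with the
#' smaller minor allele frequency is deleted (ties broken by removing the
#' lexicographically larger id). Pairs are processed in a deterministic
#' order — sorted by (chrom, position of the first SNP, position of the
#' second, ids) when positions are available in `snps`, otherwise by ids —
#' so the kept set is reproducible for a fixed input.
#'
#' @param snps `data.frame` with at least `snp_id` and `maf` (optionally
#'   `chrom`, `pos` to define processing order).
#' @param ld An `ld_pairs` table covering the SNPs; every id referenced in
#'   `ld` must be present in `snps`.
#' @param r2_threshold Strict threshold; pairs with `r2 >` this are broken.
#'   The conventional pruning level for quasi-independence is 0.2.
#' @return List with `kept` (character vector of ids) and `removed`
#'   (`data.table` of `snp_id`, `vs` the partner that triggered removal,
#'   `r2`).
#' @export
prune_ld <- function(snps, ld, r2_threshold = 0.2) {
  if (r2_threshold < 0) stop("r2_threshold must be nonnegative")
  snps <- data.table::as.data.table(snps)
  ids <- snps$snp_id
  missing_ids <- setdiff(unique(c(ld$snp_a, ld$snp_b)), ids)
  if (length(missing_ids) > 0L)
    stop("LD pairs reference SNPs absent from `snps`: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  offend <- data.table::as.data.table(ld)[r2 > r2_threshold]
  if (nrow(offend) == 0L) {
    return(list(kept = ids,
                removed = data.table::data.table(snp_id = character(),
                                                 vs = character(),
                                                 r2 = numeric())))
  }
  maf <- snps$maf[match(c(offend$snp_a, offend$snp_b), ids)]
  n <- nrow(offend)
  maf_a <- maf[seq_len(n)]; maf_b <- maf[n + seq_len(n)]
  if (!is.null(snps$pos) && !is.null(snps$chrom)) {
    ord_key <- data.table::data.table(
      chrom = snps$chrom[match(offend$snp_a, ids)],
      pos_a = snps$pos[match(offend$snp_a, ids)],
      pos_b = snps$pos[match(offend$snp_b, ids)],
      a = offend$snp_a, b = offend$snp_b)
    o <- order(ord_key$chrom, ord_key$pos_a, ord_key$pos_b,
               ord_key$a, ord_key$b)
  } else {
    o <- order(offend$snp_a, offend$snp_b)
  }
  offend <- offend[o]; maf_a <- maf_a[o]; maf_b <- maf_b[o]
  alive <- stats::setNames(rep(TRUE, length(ids)), ids)
  rem_id <- character(n); rem_vs <- character(n); rem_r2 <- numeric(n)
  k <- 0L
  for (i in seq_len(n)) {
    a <- offend$snp_a[i]; b <- offend$snp_b[i]
    if (!alive[[a]] || !alive[[b]]) next
    drop <- if (maf_a[i] < maf_b[i]) a
            else if (maf_b[i] < maf_a[i]) b
            else max(a, b)      # equal MAF: drop lexicographically larger id
    alive[[drop]] <- FALSE
    k <- k + 1L
    rem_id[k] <- drop
    rem_vs[k] <- if (drop == a) b else a
    rem_r2[k] <- offend$r2[i]
  }
  list(kept = ids[alive[ids]],
       removed = data.table::data.table(snp_id = rem_id[seq_len(k)],
                                        vs = rem_vs[seq_len(k)],
                                        r2 = rem_r2[seq_len(k)]))
}

#' Strongest LD between a query SNP and a reference set
#'
#' Returns 1 when the query itself is in the reference set, 0 when no pair
#' linking it to the set is recorded, otherwise the maximum recorded r2.
#' Used by novelty classification to decide LD-block membership.
#'
#' @param query A single SNP id.
#' @param reference_ids Character vector of reference ids.
#' @param ld An `ld_pairs` table (absent pairs are treated as r2 = 0).
#' @return A number in \[0, 1\].
#' @export
max_r2_to_set <- function(query, reference_ids, ld) {
  if (query %in% reference_ids) return(1)
  hit <- ld[(ld$snp_a == query & ld$snp_b %in% reference_ids) |
            (ld$snp_b == query & ld$snp_a %in% reference_ids)]
  if (nrow(hit) == 0L) return(0)
  max(hit$r2)
}
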
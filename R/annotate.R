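#' Read a known-association catalog
#'
#' TSV with header columns SNP, CHR, BP and optionally TRAIT; the local
#' stand-in for a GWAS-catalog snapshot of previously confirmed loci.
#'
#' @param path File path.
#' @return `data.table` with `snp_id`, `chrom`, `pos` (, `trait`).
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- data.table::fread(path, header = TRUE)
  need <- c("SNP", "CHR", "BP")
  if (!all(need %in% names(raw)))
    stop("catalog must contain columns SNP, CHR, BP")
  out <- data.table::data.table(snp_id = as.character(raw$SNP),
                                chrom = normalize_chrom(raw$CHR),
                                pos = as.integer(raw$BP))
  if ("TRAIT" %in% names(raw)) out[, trait := as.character(raw$TRAIT)]
  if (anyDuplicated(out$snp_id)) {
    warning("duplicated catalog ids collapsed to first occurrence")
    out <- out[!duplicated(out$snp_id)]
  }
  out
}

#' Classify significant SNPs as replicates or novel via LD blocks
#'
#' A significant SNP that appears in the known catalog itself is a direct
#' replicate. A SNP in the same LD block as a catalog SNP — strongest
#' recorded r2 to the catalog at or above `block_r2` — replicates that
#' known locus (`replicate-ld`). Everything else is novel. Absent LD pairs
#' count as r2 = 0, so a SNP with no recorded LD to the catalog is novel.
#'
#' @param significant Character vector of significant SNP ids.
#' @param catalog Output of [read_catalog()] (needs `snp_id`).
#' @param ld An `ld_pairs` table covering the relevant pairs.
#' @param block_r2 LD-block membership threshold; comparison is inclusive
#'   (`>=`, default 0.8), following proxy-search convention.
#' @return `data.table` with `snp_id`, `status` (`replicate-direct`,
#'   `replicate-ld`, `novel`), `best_catalog_match`, `best_r2`; attribute
#'   `counts` tabulates the statuses. Empty input gives an empty table.
#' @export
classify_novelty <- function(significant, catalog, ld, block_r2 = 0.8) {
  cat_ids <- catalog$snp_id
  n <- length(significant)
  status <- character(n); match_id <- rep(NA_character_, n); best <- numeric(n)
  for (i in seq_len(n)) {
    s <- significant[i]
    if (s %in% cat_ids) {
      status[i] <- "replicate-direct"; match_id[i] <- s; best[i] <- 1
      next
    }
    hit <- ld[(ld$snp_a == s & ld$snp_b %in% cat_ids) |
              (ld$snp_b == s & ld$snp_a %in% cat_ids)]
    if (nrow(hit) > 0L) {
      j <- which.max(hit$r2)
      best[i] <- hit$r2[j]
      match_id[i] <- if (hit$snp_a[j] == s) hit$snp_b[j] else hit$snp_a[j]
    }
    status[i] <- if (best[i] >= block_r2) "replicate-ld" else "novel"
    if (status[i] == "novel" && best[i] == 0) match_id[i] <- NA_character_
  }
  out <- data.table::data.table(snp_id = significant, status = status,
                                best_catalog_match = match_id, best_r2 = best)
  counts <- c(`replicate-direct` = sum(status == "replicate-direct"),
              `replicate-ld` = sum(status == "replicate-ld"),
              novel = sum(status == "novel"))
  data.table::setattr(out, "counts", counts)
  out
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the 1-based
#' inclusive convention used by [map_genes()] (`start_bed + 1`, `end_bed`).
#' Requires at least 4 columns (chrom, start, end, name).
#'
#' @param path BED file path.
#' @return `data.table` with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive), in file order.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- data.table::fread(path, header = FALSE)
  if (ncol(raw) < 4L) stop("gene BED needs >= 4 columns (chrom,start,end,name)")
  out <- data.table::data.table(gene = as.character(raw[[4L]]),
                                chrom = normalize_chrom(raw[[1L]]),
                                start = as.integer(raw[[2L]]) + 1L,
                                end = as.integer(raw[[3L]]))
  bad <- which(out$end < out$start)
  if (length(bad) > 0L)
    stop("malformed interval (end < start) for gene ", out$gene[bad[1L]])
  out
}

#' Map SNPs to genes by genomic interval
#'
#' A SNP maps to every gene whose flanked interval
#' `[start - flank_bp, end + flank_bp]` contains its position on the same
#' chromosome; the relation is `within` when the position falls inside the
#' gene body proper, `near` when only the flank catches it. Joint labels
#' join symbols with "/" in annotation order ("RUNX2/CLIC5"-style), the
#' convention for a SNP sitting in or between two overlapping genes.
#'
#' @param snps `data.frame` with `snp_id`, `chrom`, `pos` (1-based).
#' @param genes `data.frame` with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive; use [read_gene_bed()] for BED input).
#' @param flank_bp Nonnegative flank in bp (default 10000).
#' @return `data.table` with `snp_id`, `genes` (list column), `relations`
#'   (list column of `within`/`near`), `label` ("/"-joined, `""` when no
#'   gene matches). Unmapped SNP ids are also listed in
#'   `attr(x, "unmapped")`.
#' @export
map_genes <- function(snps, genes, flank_bp = 10000L) {
  stopifnot(flank_bp >= 0)
  if (any(genes$end < genes$start)) {
    bad <- genes$gene[which(genes$end < genes$start)[1L]]
    stop("malformed interval (end < start) for gene ", bad)
  }
  gchrom <- normalize_chrom(genes$chrom)
  schrom <- normalize_chrom(snps$chrom)
  n <- nrow(snps)
  gene_list <- vector("list", n)
  rel_list <- vector("list", n)
  label <- character(n)
  for (i in seq_len(n)) {
    sel <- which(gchrom == schrom[i] &
                 genes$start - flank_bp <= snps$pos[i] &
                 genes$end + flank_bp >= snps$pos[i])
    if (length(sel) == 0L) {
      gene_list[[i]] <- character(); rel_list[[i]] <- character()
      next
    }
    gene_list[[i]] <- genes$gene[sel]
    rel_list[[i]] <- ifelse(genes$start[sel] <= snps$pos[i] &
                              genes$end[sel] >= snps$pos[i],
                            "within", "near")
    label[i] <- paste(genes$gene[sel], collapse = "/")
  }
  out <- data.table::data.table(snp_id = snps$snp_id, genes = gene_list,
                                relations = rel_list, label = label)
  data.table::setattr(out, "unmapped", snps$snp_id[!nzchar(label)])
  out
}
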
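#' Column-mapping dialect for a summary-statistics file
#'
#' GWAS consortia name their columns differently (the lean-mass release calls
#' the effect column `Effect`, the bone-density release calls it `Beta`). A
#' dialect maps the canonical fields used throughout this package to the
#' header names of one particular file.
#'
#' @param snp,chrom,pos,beta,p,maf Header names of the required columns.
#' @param allele_ref,allele_alt Optional allele column names (`NULL` to skip).
#' @return A named list of class `"gwas_dialect"`.
#' @examples
#' gwas_dialect(beta = "Effect")   # lean-mass style
#' gwas_dialect(beta = "Beta")     # bone-density style
#' @export
gwas_dialect <- function(snp = "SNP", chrom = "CHR", pos = "BP",
                         beta = "BETA", p = "P", maf = "MAF",
                         allele_ref = NULL, allele_alt = NULL) {
  structure(list(snp = snp, chrom = chrom, pos = pos, beta = beta,
                 p = p, maf = maf,
                 allele_ref = allele_ref, allele_alt = allele_alt),
            class = "gwas_dialect")
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-delimited file with a header row, maps columns
#' through `dialect`, and screens every row against the domain invariants:
#' p-values in (0, 1], MAF in (0, 0.5], position >= 1, non-empty SNP id,
#' parseable numbers. Malformed rows are never silently kept: they are dropped
#' and accounted for, with reasons, in `attr(x, "rejected")`. Duplicated SNP
#' ids keep the first occurrence; later duplicates are rejected with reason
#' `"duplicate snp_id"`.
#'
#' @param path Path to the file.
#' @param dialect A [gwas_dialect()] mapping canonical fields to headers.
#' @param trait_name Label stored in `attr(x, "trait_name")`.
#' @return A `data.table` with columns `snp_id`, `chrom`, `pos`, `beta`,
#'   `p_value`, `maf` (plus `allele_ref`/`allele_alt` when mapped), one row
#'   per retained SNP. Attributes: `trait_name`, `rejected` (a `data.table`
#'   of `snp_id`, `reason`), `n_parsed`.
#' @export
read_summary_stats <- function(path, dialect = gwas_dialect(),
                               trait_name = basename(path)) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- data.table::fread(path, header = TRUE, colClasses = "character",
                           data.table = TRUE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  required <- c("snp", "chrom", "pos", "beta", "p", "maf")
  for (fld in required) {
    cn <- dialect[[fld]]
    if (!cn %in% names(raw)) {
      stop("required column '", cn, "' (field '", fld, "') missing in ", path)
    }
  }
  tab <- data.table::data.table(
    snp_id = raw[[dialect$snp]],
    chrom  = normalize_chrom(raw[[dialect$chrom]]),
    pos    = suppressWarnings(as.integer(raw[[dialect$pos]])),
    beta   = suppressWarnings(as.numeric(raw[[dialect$beta]])),
    p_value = suppressWarnings(as.numeric(raw[[dialect$p]])),
    maf    = suppressWarnings(as.numeric(raw[[dialect$maf]]))
  )
  if (!is.null(dialect$allele_ref) && dialect$allele_ref %in% names(raw))
    tab[, allele_ref := raw[[dialect$allele_ref]]]
  if (!is.null(dialect$allele_alt) && dialect$allele_alt %in% names(raw))
    tab[, allele_alt := raw[[dialect$allele_alt]]]

  reason <- rep(NA_character_, nrow(tab))
  mark <- function(bad, why) {
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- mark(is.na(tab$snp_id) | !nzchar(tab$snp_id), "empty snp_id")
  reason <- mark(is.na(tab$pos) | tab$pos < 1L, "bad position")
  reason <- mark(is.na(tab$p_value) | tab$p_value <= 0 | tab$p_value > 1,
                 "p out of range")
  reason <- mark(is.na(tab$maf) | tab$maf <= 0 | tab$maf > 0.5,
                 "maf out of range")
  dup <- duplicated(tab$snp_id)
  reason <- mark(dup, "duplicate snp_id")

  keep <- is.na(reason)
  rejected <- data.table::data.table(snp_id = tab$snp_id[!keep],
                                     reason = reason[!keep])
  out <- tab[keep]
  data.table::setattr(out, "trait_name", trait_name)
  data.table::setattr(out, "rejected", rejected)
  data.table::setattr(out, "n_parsed", nrow(tab))
  out
}

#' Normalize chromosome labels for comparison
#'
#' `"chr1"`, `"Chr1"` and `"1"` all refer to the same chromosome; merging and
#' sorting use the stripped, upper-cased form (`"1"`, `"X"`, ...).
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chrom <- function(x) {
  toupper(sub("^[Cc][Hh][Rr]", "", as.character(x)))
}

#' Direction code of a signed effect size
#'
#' `"+"` for beta > 0 (positive effect of the reference allele), `"-"` for
#' beta < 0, `"0"` when beta is exactly zero or missing. Non-finite betas are
#' treated as missing and flagged via a warning.
#'
#' @param beta Numeric vector of signed effect sizes.
#' @return Character vector in `{"+", "-", "0"}`.
#' @examples
#' assign_direction(c(0.12, -0.05, 0))  # "+" "-" "0"
#' @export
assign_direction <- function(beta) {
  nonfin <- !is.na(beta) & !is.finite(beta)
  if (any(nonfin)) {
    warning(sum(nonfin), " non-finite beta value(s) treated as missing")
    beta[nonfin] <- NA_real_
  }
  out <- rep("0", length(beta))
  out[!is.na(beta) & beta > 0] <- "+"
  out[!is.na(beta) & beta < 0] <- "-"
  out
}

#' Merge two summary-statistics tables on common SNPs
#'
#' Forms the exact intersection of the two tables' SNP id sets and pairs up
#' their p-values and effect directions: `p1`/`dir1` come from `table_a` (the
#' principal trait), `p2`/`dir2` from `table_b` (the conditional trait).
#' Positional metadata (chromosome, position, MAF) is taken from `table_a`;
#' position discrepancies against `table_b` are counted in
#' `attr(x, "pos_discrepancies")`. Rows are ordered by (chrom, pos, snp_id)
#' so the merge is deterministic.
#'
#' @param table_a,table_b Tables from [read_summary_stats()] (or any
#'   data.frame with `snp_id`, `chrom`, `pos`, `beta`, `p_value`, `maf`).
#' @param strict_alleles If `TRUE` and both tables carry allele columns,
#'   allele mismatches between the files are counted and reported in
#'   `attr(x, "allele_mismatches")`. No beta flipping is ever attempted.
#' @return A `data.table` with columns `snp_id`, `chrom`, `pos`, `p1`, `p2`,
#'   `dir1`, `dir2`, `maf`.
#' @export
harmonize <- function(table_a, table_b, strict_alleles = FALSE) {
  a <- data.table::as.data.table(table_a)
  b <- data.table::as.data.table(table_b)
  stopifnot(!anyDuplicated(a$snp_id), !anyDuplicated(b$snp_id))
  common <- intersect(a$snp_id, b$snp_id)
  if (length(common) == 0L) stop("no SNPs common to the two tables")
  a2 <- a[match(common, a$snp_id)]
  b2 <- b[match(common, b$snp_id)]
  merged <- data.table::data.table(
    snp_id = common,
    chrom = a2$chrom,
    pos = a2$pos,
    p1 = a2$p_value,
    p2 = b2$p_value,
    dir1 = assign_direction(a2$beta),
    dir2 = assign_direction(b2$beta),
    maf = a2$maf
  )
  n_pos_disc <- sum(a2$pos != b2$pos | normalize_chrom(a2$chrom) !=
                      normalize_chrom(b2$chrom), na.rm = TRUE)
  n_allele_mm <- 0L
  if (strict_alleles && all(c("allele_ref") %in% names(a2)) &&
      all(c("allele_ref") %in% names(b2))) {
    n_allele_mm <- sum(toupper(a2$allele_ref) != toupper(b2$allele_ref),
                       na.rm = TRUE)
  }
  data.table::setorder(merged, chrom, pos, snp_id)
  data.table::setattr(merged, "pos_discrepancies", n_pos_disc)
  data.table::setattr(merged, "allele_mismatches", n_allele_mm)
  merged
}

#' Write a merged pair table as TSV
#'
#' Columns: SNP, CHR, BP, P1, P2, DIR1, DIR2, MAF.
#'
#' @param merged Output of [harmonize()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_merged <- function(merged, path) {
  out <- data.table::data.table(
    SNP = merged$snp_id, CHR = merged$chrom, BP = merged$pos,
    P1 = merged$p1, P2 = merged$p2, DIR1 = merged$dir1, DIR2 = merged$dir2,
    MAF = merged$maf)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write a summary-statistics table in the canonical layout
#'
#' Header SNP/CHR/BP/BETA/P/MAF; readable back with the default
#' [gwas_dialect()]. Round-trips all retained records exactly.
#'
#' @param tab Output of [read_summary_stats()] or [simulate_joint_gwas()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(tab, path) {
  out <- data.table::data.table(
    SNP = tab$snp_id, CHR = tab$chrom, BP = tab$pos,
    BETA = tab$beta, P = tab$p_value, MAF = tab$maf)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
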
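#' Wilcoxon rank-sum comparison of two expression groups
#'
#' Rank-based non-parametric two-group comparison with no normality
#' assumption, as used to test whether a candidate gene's mRNA level
#' differs between groups (e.g. 16 young vs 12 old muscle biopsies). The
#' exact null distribution (full enumeration over rank assignments) is used
#' when the pooled sample size is at most 20 and there are no ties;
#' otherwise mid-ranks with the normal approximation, tie correction and
#' continuity correction. The `method` field records which path ran.
#'
#' @param group_a,group_b Numeric expression values, both nonempty.
#' @param gene Optional gene label carried into the result.
#' @return A one-row `data.table`: `gene`, `statistic` (rank-sum W of group
#'   A, Mann-Whitney form), `p_value` (two-sided), `n_a`, `n_b`, `method`
#'   (`"exact"` or `"normal-approx"`).
#' @export
rank_sum_test <- function(group_a, group_b, gene = NA_character_) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty")
  n_tot <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- n_tot <= 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  data.table::data.table(
    gene = gene,
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_a = length(group_a), n_b = length(group_b),
    method = if (exact) "exact" else "normal-approx")
}

#' Correlation of expression with a continuous trait
#'
#' Correlation of a gene's per-sample expression against a continuous
#' phenotype (e.g. whole-body bone mineral density across 84 bone
#' biopsies), with a two-sided p-value from the t-distribution on n-2
#' degrees of freedom. Pairs with a missing value in either vector are
#' dropped first. Zero variance in either vector makes the coefficient
#' undefined; such genes are flagged (`defined = FALSE`) rather than
#' returning NaN.
#'
#' @param expression,trait Equal-length numeric vectors (>= 3 complete
#'   pairs).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param gene Optional gene label.
#' @return One-row `data.table`: `gene`, `statistic` (r), `p_value`, `n`,
#'   `method`, `defined`.
#' @export
trait_correlation <- function(expression, trait,
                              method = c("pearson", "spearman"),
                              gene = NA_character_) {
  method <- match.arg(method)
  if (length(expression) != length(trait))
    stop("expression and trait must have equal length")
  ok <- is.finite(expression) & is.finite(trait)
  x <- expression[ok]; y <- trait[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(data.table::data.table(gene = gene, statistic = NA_real_,
                                  p_value = NA_real_, n = length(x),
                                  method = paste0("correlation-", method),
                                  defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided",
                                         exact = FALSE))
  data.table::data.table(gene = gene, statistic = unname(ct$estimate),
                         p_value = ct$p.value, n = length(x),
                         method = paste0("correlation-", method),
                         defined = TRUE)
}

#' Read an expression matrix with sample metadata
#'
#' Expression: TSV, first column gene symbols, remaining columns one per
#' sample. Metadata: TSV with columns `sample` and `group` and/or `trait`.
#'
#' @param expr_path,meta_path File paths.
#' @return List with `expr` (numeric matrix, genes x samples) and `meta`
#'   (`data.table`), samples aligned.
#' @export
read_expression <- function(expr_path, meta_path) {
  raw <- data.table::fread(expr_path, header = TRUE)
  genes <- as.character(raw[[1L]])
  if (any(!nzchar(genes) | is.na(genes))) stop("missing gene ids")
  expr <- as.matrix(raw[, -1L, with = FALSE])
  rownames(expr) <- genes
  meta <- data.table::fread(meta_path, header = TRUE)
  if (!"sample" %in% names(meta)) stop("metadata needs a 'sample' column")
  miss <- setdiff(colnames(expr), meta$sample)
  if (length(miss) > 0L)
    stop("samples without metadata: ", paste(utils::head(miss, 5), collapse = ", "))
  meta <- meta[match(colnames(expr), meta$sample)]
  list(expr = expr, meta = meta)
}

#' Per-gene expression validation report
#'
#' Applies [rank_sum_test()] across a two-group design and/or
#' [trait_correlation()] against a continuous trait, one row per gene.
#' Following common practice for targeted candidate-gene validation, p < 0.05
#' is reported as nominally significant with no multiple-testing correction
#' by default; `adjust = "BH"` adds a Benjamini-Hochberg column.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param meta `data.table` with `sample` and `group` (two levels) and/or
#'   `trait`.
#' @param genes Gene subset (default all rows).
#' @param cor_method Passed to [trait_correlation()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.table`, one row per gene x statistic, with a `nominal_sig`
#'   flag (and `p_adj` when requested).
#' @export
validate_expression <- function(expr, meta, genes = rownames(expr),
                                cor_method = "pearson",
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  genes <- intersect(genes, rownames(expr))
  res <- list()
  if ("group" %in% names(meta) && length(unique(meta$group)) == 2L) {
    lv <- sort(unique(meta$group))
    res$ranksum <- data.table::rbindlist(lapply(genes, function(g) {
      rank_sum_test(expr[g, meta$group == lv[1L]],
                    expr[g, meta$group == lv[2L]], gene = g)
    }), fill = TRUE)
  }
  if ("trait" %in% names(meta)) {
    res$corr <- data.table::rbindlist(lapply(genes, function(g) {
      trait_correlation(expr[g, ], meta$trait, method = cor_method, gene = g)
    }), fill = TRUE)
  }
  if (length(res) == 0L) stop("metadata provides neither a two-level group nor a trait")
  out <- data.table::rbindlist(res, fill = TRUE)
  out[, nominal_sig := !is.na(p_value) & p_value < 0.05]
  if (adjust == "BH")
    out[, p_adj := stats::p.adjust(p_value, method = "BH"), by = method]
  out
}
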
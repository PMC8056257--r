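#' Per-SNP conditional false discovery rate
#'
#' The conditional FDR of SNP i for the principal trait, given the
#' conditional trait, is estimated by empirical counting over the merged
#' table:
#' \deqn{\widehat{\mathrm{cFDR}}_i = \min\!\Big(1,\;
#'   p_i \cdot \frac{\#\{j : q_j \le q_i\}}{\#\{j : p_j \le p_i
#'   \wedge q_j \le q_i\}}\Big)}
#' where \eqn{p} is the principal-trait p-value and \eqn{q} the
#' conditional-trait p-value. Counts are inclusive (they contain SNP i
#' itself), so the denominator is at least 1 and the single-SNP case reduces
#' to the SNP's own p-value. The null proportion is conservatively taken as
#' 1 and values are capped at 1. Ties in either p-value share the largest
#' qualifying count. With every conditional p equal to 1 the estimator
#' collapses to the unconditional Benjamini–Hochberg-style quantity
#' `p * N / rank` (see [unconditional_fdr()]).
#'
#' The estimator assumes quasi-independent SNPs; LD-prune the merged table
#' (r2 > 0.2, [prune_ld()]) before calling.
#'
#' @param merged Output of [harmonize()], or any data.frame with `p1`, `p2`
#'   in (0, 1].
#' @param principal Which trait is principal: `1` conditions trait 1 on
#'   trait 2 (`p = p1, q = p2`), `2` the reverse.
#' @param monotone If `TRUE`, enforce lookup-table semantics: after sorting
#'   by (q, p) the running minimum makes cFDR non-increasing in significance.
#'   Default `FALSE` (plain per-SNP counting, exactly oracle-checkable).
#' @return Numeric vector of cFDR values in (0, 1], aligned with the rows of
#'   `merged`.
#' @examples
#' m <- data.frame(p1 = c(.001, .02, .04, .5, .9),
#'                 p2 = c(.01, .03, .5, .6, .2))
#' compute_cfdr(m, principal = 1)
#' @export
compute_cfdr <- function(merged, principal = 1, monotone = FALSE) {
  stopifnot(principal %in% c(1, 2))
  if (nrow(merged) == 0L) stop("merged table is empty")
  p <- if (principal == 1) merged$p1 else merged$p2
  q <- if (principal == 1) merged$p2 else merged$p1
  check_pvalues(p); check_pvalues(q)
  n_q <- rank(q, ties.method = "max")           # #{j : q_j <= q_i}
  n_joint <- joint_dominance_count(p, q)        # #{j : p_j <= p_i & q_j <= q_i}
  val <- pmin(1, p * n_q / n_joint)
  if (monotone) {
    # lookup-table semantics: a more significant principal p never receives
    # a larger cFDR than a less significant one (running minimum)
    o <- order(p, decreasing = TRUE)
    val[o] <- cummin(val[o])
  }
  val
}

check_pvalues <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  invisible(TRUE)
}

#' Conjunction cFDR of two conditioning directions
#'
#' Elementwise maximum of the two direction-specific cFDR vectors. The
#' conjunction value estimates the probability that the SNP is associated
#' with neither of the two traits, and is used to call pleiotropic SNPs.
#'
#' @param cfdr_a,cfdr_b Equal-length numeric vectors aligned by SNP.
#' @return Numeric vector of ccFDR values.
#' @examples
#' compute_ccfdr(0.01, 0.04)  # 0.04
#' @export
compute_ccfdr <- function(cfdr_a, cfdr_b) {
  if (length(cfdr_a) != length(cfdr_b))
    stop("cFDR vectors must have equal length")
  pmax(cfdr_a, cfdr_b)
}

#' Unconditional empirical FDR baseline
#'
#' `FDR_i = min(1, p_i * N / rank_i)` with rank the inclusive count of
#' p-values at or below `p_i` (ties share the larger count). This is the
#' single-trait baseline the conditional method is compared against, and is
#' exactly [compute_cfdr()] with every conditional p-value set to 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of FDR estimates.
#' @export
unconditional_fdr <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  check_pvalues(p)
  pmin(1, p * length(p) / rank(p, ties.method = "max"))
}

#' Full cFDR/ccFDR result table
#'
#' Runs [compute_cfdr()] in both conditioning directions on a merged pair
#' table, forms the conjunction ccFDR, and attaches significance calls at
#' the threshold (strict `<`).
#'
#' @param merged Output of [harmonize()].
#' @param threshold Significance cut-off (default 0.05).
#' @param monotone Passed to [compute_cfdr()].
#' @return `data.table` with the merged columns plus `cfdr_1_given_2`,
#'   `cfdr_2_given_1`, `ccfdr`, `sig_1_given_2`, `sig_2_given_1`,
#'   `sig_conjunction`.
#' @export
cfdr_table <- function(merged, threshold = 0.05, monotone = FALSE) {
  c12 <- compute_cfdr(merged, principal = 1, monotone = monotone)
  c21 <- compute_cfdr(merged, principal = 2, monotone = monotone)
  out <- data.table::as.data.table(merged)
  out[, `:=`(cfdr_1_given_2 = c12,
             cfdr_2_given_1 = c21,
             ccfdr = compute_ccfdr(c12, c21))]
  out[, `:=`(sig_1_given_2 = cfdr_1_given_2 < threshold,
             sig_2_given_1 = cfdr_2_given_1 < threshold,
             sig_conjunction = ccfdr < threshold)]
  data.table::setattr(out, "threshold", threshold)
  out
}

#' Manhattan-plot data for cFDR or ccFDR values
#'
#' Transforms per-SNP values to `y = -log10(value)` and flags points above
#' the significance reference line. The emitted line height is
#' `-log10(threshold)` rounded to one decimal (1.3 for the conventional
#' 0.05 cut-off), matching how the line is drawn on the plot; the
#' `above_line` flag itself uses the exact threshold.
#'
#' @param values Numeric vector of cFDR/ccFDR values in (0, 1].
#' @param threshold Significance cut-off (default 0.05).
#' @param snp_id,chrom,pos Optional per-SNP annotation columns.
#' @return `data.table` with `snp_id`, `chrom`, `pos`, `y`, `above_line`;
#'   attribute `line` holds the rounded line height.
#' @export
manhattan_table <- function(values, threshold = 0.05,
                            snp_id = NULL, chrom = NULL, pos = NULL) {
  if (any(!is.finite(values) | values <= 0))
    stop("cFDR values must be positive to take -log10")
  n <- length(values)
  out <- data.table::data.table(
    snp_id = if (is.null(snp_id)) as.character(seq_len(n)) else snp_id,
    chrom = if (is.null(chrom)) NA_character_ else chrom,
    pos = if (is.null(pos)) NA_integer_ else pos,
    y = -log10(values),
    above_line = values < threshold)
  data.table::setattr(out, "line", round(-log10(threshold), 1))
  out
}
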
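#' Stratified (conditional) Q-Q curves
#'
#' For each conditional-trait cutoff `t`, takes the stratum of SNPs whose
#' conditional p-value is at most `t` and plots the principal-trait p-values
#' against their empirical quantiles: within a stratum of size `n`, the k-th
#' smallest principal p gets quantile `q = k/(n+1)` (the `"k/(n+1)"`
#' convention avoids `-log10(0)` at the extreme order statistic;
#' `"(k-0.5)/n"` is available). Each point is
#' `(x, y) = (-log10 q, -log10 p)`. Under no pleiotropy all curves follow
#' the identity line; upward/leftward deflection of the stricter strata is
#' the visual signature of pleiotropic enrichment.
#'
#' @param merged Output of [harmonize()].
#' @param principal `1` or `2`: which trait's p-values form the curve; the
#'   other trait defines the strata.
#' @param thresholds Descending conditional cutoffs in (0, 1]. The leading 1
#'   gives the all-SNP reference stratum.
#' @param quantile_rule `"k/(n+1)"` (default) or `"(k-0.5)/n"`.
#' @return Long-format `data.table` with columns `threshold`, `x`, `y`, `n`
#'   (stratum size), sorted by threshold (descending) then `x` ascending.
#'   Empty strata are omitted with a warning.
#' @export
stratified_qq <- function(merged, principal = 1,
                          thresholds = c(1, 0.1, 0.01, 0.001),
                          quantile_rule = c("k/(n+1)", "(k-0.5)/n")) {
  quantile_rule <- match.arg(quantile_rule)
  if (nrow(merged) == 0L) stop("merged table is empty")
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  p <- if (principal == 1) merged$p1 else merged$p2
  q <- if (principal == 1) merged$p2 else merged$p1
  thresholds <- sort(thresholds, decreasing = TRUE)
  out <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    ps <- sort(p[q <= t])
    n <- length(ps)
    if (n == 0L) {
      warning("stratum at conditional threshold ", t, " is empty; omitted")
      next
    }
    k <- seq_len(n)
    eq <- if (quantile_rule == "k/(n+1)") k / (n + 1) else (k - 0.5) / n
    out[[i]] <- data.table::data.table(
      threshold = t, x = -log10(eq), y = -log10(ps), n = n)
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, -threshold, x)
  res
}

#' Enrichment deflection area of stratified Q-Q curves
#'
#' Quantifies the leftward/upward deviation seen on a conditional Q-Q plot
#' as a scalar per stratum: the trapezoidal area between the stratum curve
#' and the reference (all-SNP) curve, after linear interpolation onto the
#' overlapping `-log10(q)` range, normalized by the width of that range.
#' Positive values mean the stratum lies above the reference (enrichment);
#' the reference stratum scores exactly 0 against itself.
#'
#' @param strata Output of [stratified_qq()].
#' @param reference Threshold identifying the reference stratum (default 1,
#'   the all-SNP stratum).
#' @param grid_n Number of interpolation grid points.
#' @return `data.table` with `threshold`, `deflection`, `n`, and a logical
#'   `defined` (strata with fewer than 2 points cannot be interpolated and
#'   are flagged undefined).
#' @export
enrichment_area <- function(strata, reference = 1, grid_n = 512L) {
  ths <- unique(strata$threshold)
  if (!reference %in% ths) stop("reference stratum not present")
  ref <- strata[strata$threshold == reference, ]
  out <- data.table::data.table(threshold = ths, deflection = NA_real_,
                                n = NA_integer_, defined = FALSE)
  for (i in seq_along(ths)) {
    s <- strata[strata$threshold == ths[i], ]
    data.table::set(out, i, "n", s$n[1L])
    if (nrow(s) < 2L || nrow(ref) < 2L) next
    lo <- max(min(s$x), min(ref$x))
    hi <- min(max(s$x), max(ref$x))
    if (hi <= lo) next
    gx <- seq(lo, hi, length.out = grid_n)
    ys <- stats::approx(s$x, s$y, xout = gx, ties = mean)$y
    yr <- stats::approx(ref$x, ref$y, xout = gx, ties = mean)$y
    diff <- ys - yr
    area <- sum((diff[-1L] + diff[-grid_n]) / 2 * base::diff(gx))
    data.table::set(out, i, "deflection", area / (hi - lo))
    data.table::set(out, i, "defined", TRUE)
  }
  data.table::setattr(out, "reference", reference)
  out
}
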
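---
title: "Conditional FDR for paired GWAS summary statistics: model, estimator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional FDR for paired GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiocfdr)
```

## The problem and the model

Two traits measured in independent GWAS cohorts — say lean muscle mass and
bone mineral density — often share causal variants. For a SNP with p-value
$p$ for the principal trait and $q$ for the conditional trait, the
conditional FDR asks: *given that both p-values are at least this small,
what is the probability the SNP is null for the principal trait?* When the
two traits share architecture, small $q$ is informative about non-nullness
for the principal trait, and ranking SNPs by cFDR instead of $p$ alone
recovers associations that the single-trait scan leaves below threshold.

`pleiocfdr` estimates this quantity by empirical counting on the merged
per-SNP table:

$$\widehat{\mathrm{cFDR}}_i \;=\; \min\!\left(1,\;
  p_i\,\frac{\#\{j : q_j \le q_i\}}{\#\{j : p_j \le p_i \wedge q_j \le q_i\}}
\right).$$

The numerator-to-denominator ratio is the reciprocal of the empirical
conditional CDF of $p$ within the stratum $q \le q_i$: it converts the
nominal p-value into an estimate of the false-discovery rate among SNPs at
least as extreme in both coordinates. The implied null proportion is fixed
at 1, the conservative choice; no attempt is made to estimate it. The
conjunction statistic
$\mathrm{ccFDR}_i = \max\{\widehat{\mathrm{cFDR}}_i(1|2),
\widehat{\mathrm{cFDR}}_i(2|1)\}$ upper-bounds the probability that the SNP
is associated with neither trait and is the basis for pleiotropic calls.

Assumptions worth keeping in view:

* **Quasi-independent SNPs.** The counts treat rows as exchangeable, so
  dense LD inflates the effective weight of large haplotype blocks. The
  pipeline therefore prunes at $r^2 > 0.2$ before estimation, dropping the
  lower-MAF member of each offending pair.
* **No sample overlap.** Correlation between the two sets of test
  statistics induced by shared individuals would masquerade as pleiotropy.
  The two cohorts are assumed independent; the package does not model or
  correct overlap.
* **Valid marginal p-values.** Genomic control or any other inflation
  correction is assumed done upstream in the original scans.

## What thresholding the estimator does — and does not — guarantee

Calling every SNP with $\widehat{\mathrm{cFDR}} < \alpha$ is the field's
standard practice, and each *individual* value is a conservative estimate
of the quadrant-wise false-discovery rate. The *set-level* false-discovery
proportion of the calls, however, is not exactly controlled at $\alpha$:
the selection region is a data-dependent union of quadrants, and genuine
pleiotropic enrichment in the low-$q$ strata deflates the cFDR of null SNPs
that happen to have moderately small $q$. Under the synthetic conditions
used by `scripts/acceptance.R` (94% nulls, 2% per-trait specifics, 2%
pleiotropic SNPs with effect-mean SD 3 and effect correlation 0.8), that
script measures a realized FDP of roughly twice the nominal 0.05 at the
0.05 call threshold, stable across replicates — consistent with how this
estimator lineage is known to behave. Exact set-level control requires a
different construction (rejection-curve/v-value methods) that is outside
this package's scope. Users who need guaranteed FDR control should treat
cFDR calls as a prioritization, not a calibrated error rate; users
comparing against the unconditional baseline should note that
`unconditional_fdr()` thresholded the same way has the same per-SNP (not
set-level) interpretation, making the power comparison like-for-like.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| cFDR/ccFDR significance cut-off | 0.05 | probability | conventional FDR level; the Manhattan reference line is $-\log_{10}(0.05) \approx 1.3$ |
| LD-pruning threshold | 0.2 | $r^2$ | standard level for quasi-independence of markers; comparison is strict (`>`) |
| LD-block threshold for novelty | 0.8 | $r^2$ | proxy-search convention for "same signal"; comparison is inclusive (`>=`), configurable |
| Q–Q strata | 1, 0.1, 0.01, 0.001 | conditional p | the customary ladder of conditioning stringency; threshold 1 is the all-SNP reference |
| Gene-mapping flank | 10 000 | bp | captures promoter-proximal SNPs without swallowing neighboring genes |
| Quantile plotting position | $k/(n+1)$ | — | keeps the extreme order statistic off $-\log_{10}(0)$; $(k-0.5)/n$ available |

## Numerical choices

* **Inclusive counts.** Both counts include SNP $i$ itself, so the
  denominator is never zero and a single-SNP table returns its own
  p-value. Ties in either coordinate share the largest qualifying count
  (`rank(..., ties.method = "max")` semantics on both axes).
* **Exact counting, optionally monotonized.** The default output is the
  plain per-SNP statistic, which an $O(N^2)$ brute-force count reproduces
  exactly — the production path is an $O(N \log N)$ Fenwick-tree sweep in
  C++, and the test suite asserts bit-exact agreement between the two on
  randomized tables with heavy ties. `monotone = TRUE` applies a running
  minimum in order of decreasing $p$ for users who want lookup-table
  semantics (a more significant p-value never receives a larger cFDR);
  it only ever lowers values.
* **Direction codes.** Beta exactly 0 (or missing) maps to direction
  `"0"` and the row participates in all statistics; only the sign is ever
  interpreted, never the magnitude.
* **Pruning determinism.** Offending pairs are processed sorted by
  (chromosome, position of the first SNP, position of the second, ids);
  the lower-MAF member is removed, with exact MAF ties dropping the
  lexicographically larger id. The kept set is verified edge-free by an
  exhaustive scan in the tests, and re-pruning the kept set removes
  nothing.
* **Degenerate inputs.** p-values outside $(0,1]$, empty merges,
  zero-variance dosage columns, groups of size zero and malformed gene
  intervals are hard errors or explicit flags (`defined = FALSE` for a
  zero-variance correlation), never silent NaN propagation.
* **BED conversion.** Gene intervals arrive 0-based half-open and are
  converted once to 1-based inclusive; a SNP at the raw BED start
  coordinate is outside the gene, at start+1 inside. The conversion is
  covered by tests.

## The synthetic generator

`simulate_joint_gwas()` works at the z-score level: each SNP draws a latent
component — null `00`, trait-1-only `10`, trait-2-only `01`, pleiotropic
`11` — with configured fractions; non-null effect means are
$N(0, \sigma^2)$ with $\sigma = 3$ by default, pleiotropic means drawn
jointly with correlation $\rho = 0.8$ (negative $\rho$ models
opposite-direction pleiotropy, which real pleiotropic loci also show); the
observed z adds unit Gaussian noise and two-sided p-values are
$2\Phi(-|z|)$. A z-score mixture rather than a genotype-level simulation is
deliberate: the estimator consumes only p-values, so genotype realism would
add cost without exercising more code. LD for the pruning and novelty
stages comes from a separate latent-factor dosage panel
(`simulate_ld_panel()`): SNPs within a block load equally on a shared
factor so the expected pairwise within-block $r^2$ equals the configured
level (0.9 by default across blocks of 5 SNPs and 200 individuals), and
blocks are mutually independent. `simulate_expression()` emulates a
two-group biopsy design (16 vs 12 by default) with optional mean shifts
and a linear coupling to a continuous phenotype. All randomness flows from
one seed through fixed per-stage offsets, so each stage is independently
reproducible.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: realistic human LD maps and ancestry
structure; sample-overlap correlation; p-value inflation needing genomic
control; allele-frame mismatches between files (the merge is id-based and
the optional strict mode only logs allele disagreements); probe-level
expression data (gene-level input is assumed pre-aggregated).

One subtlety of the exclusive four-component mixture matters for
interpreting the enrichment diagnostic: with the pleiotropic fraction set
to zero but trait-specific fractions kept, a SNP selected by the
conditional trait can never be non-null for the principal trait, so strict
strata are genuinely *depleted* of principal-trait signal and the expected
Q–Q deflection is slightly negative, not zero. The test suite accordingly
checks one-sidedly that no spurious *enrichment* appears in that setting,
and checks the two-sided zero only on fully null data, where it is the
true expectation.

## Problem sizes used by the test suite

The suite favors many medium-size randomized instances over few large
ones: oracle-equivalence on one hundred tables of up to 500 SNPs
(brute-force checked exactly), enrichment and power properties on 20,000-
to 50,000-SNP simulations with 8–20 replicates, and the false-discovery
measurement on 25 replicates of 100,000 SNPs. These sizes give Monte-Carlo
standard errors well inside the asserted bands while keeping a full run in
the tens of seconds.

## Known limitations

* Set-level FDR control at the call threshold is approximate (see above);
  the measured excess under strong enrichment is about a factor of two.
* The pruning order is a documented in-package convention; PLINK's windowed
  `--indep-pairwise` visits pairs differently, so kept-set membership can
  differ from a PLINK run even at the same threshold.
* Novelty classification is only as good as the supplied LD pair set:
  absent pairs count as $r^2 = 0$, so an under-populated panel inflates
  "novel" calls.
* Multi-allelic and strand-ambiguous SNPs are merged by id like any other;
  strict mode logs allele mismatches but nothing is flipped or dropped.
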
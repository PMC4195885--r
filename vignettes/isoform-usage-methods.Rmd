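---
title: "Estimating and testing differential isoform usage: models and methods"
author: "isoUsage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and testing differential isoform usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoUsage)
```

# The problem

A gene with $K$ annotated isoforms distributes its transcript output across
them. The *isoform usage* of the gene in a sample is the composition
$\theta = (\theta_1, \dots, \theta_K)$, $\theta_k \ge 0$, $\sum_k \theta_k = 1$:
the fraction of the gene's transcripts carrying each isoform. Differential
isoform usage between two groups of samples (tissues, conditions, genotypes)
is a change in this composition, distinct from differential expression of the
gene or of any single isoform.

Because usage is compositional, comparisons should respect Aitchison
geometry, in which distance is built from log-ratios and therefore tracks
fold-changes of proportions. A shift of $0.05 \to 0.10$ in a minor isoform
doubles it, while $0.30 \to 0.35$ is a modest change; Euclidean distance
treats the two identically, Aitchison distance does not
(`aitchison_distance()` returns 0.609 versus 0.238 for these two examples
with a common third part of 0.40).

The analysis has two steps per gene:

1. **Estimate** $\hat\theta_{ij}$ in each sample $j$ of each group $i$ from
   paired-end alignments, by maximum likelihood (EM).
2. **Test** equality of the two group mean compositions after mapping
   estimates to $\mathbb{R}^{K-1}$ with an isometric log-ratio (ilr)
   transform, using multivariate Behrens–Fisher tests.

# Step 1: the read-mixture likelihood

## Compatibility and implied fragment lengths

For a gene with isoform lengths $l_k$ and $N$ aligned pairs, each pair $n$
either is or is not compatible with isoform $k$: every aligned block of both
mates must lie inside single exons of $k$ and consecutive blocks of a mate
must abut in transcript coordinates (alignment gaps must coincide with the
isoform's introns). For compatible pairs, $l_k^n$ is the implied fragment
length — the inclusive transcript-coordinate span from the 5'-most base of
one mate to the 3'-most base of the other; $l_k^n = 0$ marks incompatibility.
Pairs compatible with no isoform are dropped and counted (there is no noise
class in the model). Compatibility is strand-symmetric, so it is computed on
genomic-forward transcript offsets for both strands.

## Fragment placement model

Let $f(\cdot)$ be the fragment-length distribution. A fragment from isoform
$k$ is modelled as a uniform draw over all valid (length, start) placements
weighted by $f$: a length-$l$ fragment has $l_k - l + 1$ possible starts, so

$$P(L = l \mid I = k) = \frac{f(l)\,(l_k - l + 1)}{Z_k}, \qquad
  P(R = r_n \mid I = k, L = l_k^n) = \frac{1}{l_k - l_k^n + 1},$$

where $Z_k = \sum_l f(l) \max(l_k - l + 1, 0)$ is the *effective length* of
isoform $k$. The net per-read weight is $a_{nk} = f(l_k^n) / Z_k$ for
compatible entries and 0 otherwise. No junction-overhang restriction is
imposed on split reads. This uniform-placement model is the one under which
the read-origin probabilities $p_k$ and the usage $\theta_k$ are linked by
the exact identity $p_k = \theta_k Z_k / \sum_j \theta_j Z_j$, which we rely
on below; a model without the $Z_k$ normalisation would not invert cleanly.

$f$ is estimated per sample, pooled across all genes, from *unambiguous*
pairs only — those whose compatible isoforms all imply the same length
(single-isoform genes, or mates within exons common to all isoforms). The
empirical pmf is truncated at the 0.001/0.999 quantiles (configurable), with
optional moving-average smoothing. Below `min_fragments` (default 1000)
unambiguous pairs, a discretized normal fallback (defaults: mean 250 nt,
sd 25 nt, a typical paired-end insert distribution) is used with a warning.

## EM and the p-to-theta conversion

With mixture weights $p$ on the $K$ isoforms, the log-likelihood is
$\ell(p) = \sum_n \log \sum_k p_k a_{nk}$. Treating the isoform of origin as
latent, EM iterates responsibilities
$w_{nk} = p_k a_{nk} / \sum_j p_j a_{nj}$ and $p_k \leftarrow \bar w_{\cdot k}$.
Numerical choices:

* start at uniform $p = (1/K, \dots)$, plus one extra Dirichlet(1) random
  start by default (best likelihood kept) to guard the rare ridges created
  by near-identical isoforms;
* convergence on $\max_k |\Delta p_k| < 10^{-6}$ (the scale the updates live
  on), capped at 1000 iterations with a warning and the best iterate;
* genes whose isoforms have numerically identical weight columns are
  non-identifiable; the symmetric EM fixed point is reported with a
  `non_identifiable` flag rather than an arbitrary tie-break.

Usage follows by inverting the length bias:
$\hat\theta_k \propto \hat p_k / Z_k$, renormalised. Genes with fewer than
`min_reads` (default 10) usable pairs are flagged; genes with none are
reported as `no_usable_reads` and excluded from testing.

# Step 2: testing equal mean usage

## Hierarchical model

Sample-level estimates vary around sample means (estimation noise,
coverage-dependent), and sample means vary around the group mean
(biological replication). Both stages are modelled as normal on ilr
coordinates — a logistic-normal model on the simplex. The tests use the
marginal consequence: within group $i$, ilr-transformed estimates are
i.i.d. normal with some group covariance that *differs between groups*.
Testing equal group means is then the multivariate Behrens–Fisher problem.

## Zero handling

ilr needs strictly positive parts. Isoforms estimated at zero in *every*
sample of both groups are removed (and named in the result flags); if one
isoform remains, the gene is untestable. Remaining zeros are replaced by
`eps` (default $10^{-4}$) and the vector re-closed — applied after the
all-zero reduction and before ilr. Near-zero usage in both groups can
dominate log-ratio distances; raising `eps` (say to 0.01) is the practical
control for that, and sensitivity of the gene list to `eps` is worth
checking in real analyses.

## The three tests

With $X$ ($J_0 \times d$) and $Y$ ($J_1 \times d$), $d = K - 1$,
$\tilde S = S_1/J_0 + S_2/J_1$:

* **KY** (`ky_test()`): $T^2 = \bar d' \tilde S^{-1} \bar d$ with the
  modified Nel–van der Merwe approximate degrees of freedom
  $\nu = (d + d^2) / \sum_i \frac{1}{J_i - 1}\left[\mathrm{tr}((\tilde S_i
  \tilde S^{-1})^2) + \mathrm{tr}^2(\tilde S_i \tilde S^{-1})\right]$ and
  $T^2 (\nu - d + 1)/(\nu d) \sim F(d, \nu - d + 1)$. At $d = 1$ this *is*
  Welch's t-test (exposed separately as `welch_test()`). Requires
  $\tilde S$ positive definite, hence $d < \min(J_0, J_1)$; otherwise the
  result is flagged `ky_inapplicable`.
* **CQ** (`cq_test()`): the cross-product statistic of Chen & Qin, which
  avoids covariance inversion entirely, standardised by their leave-out
  trace estimators of $\mathrm{tr}(\Sigma_i^2)$ and
  $\mathrm{tr}(\Sigma_1\Sigma_2)$; upper-tail normal p-value. For groups of
  size 2 the unbiased trace estimator does not exist and a plug-in
  $\mathrm{tr}(S^2)$ is substituted with a `plugin_trace` flag.
* **SKK** (`skk_test()`, the default): the diagonally standardised form
  $q = \bar d' \hat D^{-1} \bar d$, $\hat D = \mathrm{diag}(\tilde S)$,
  centred at $d$ and scaled by
  $\sqrt{2\,(\mathrm{tr}\hat R^2 - d^2/n)\,c_{d,n}}$ with
  $\hat R = \hat D^{-1/2} \tilde S \hat D^{-1/2}$,
  $c_{d,n} = 1 + \mathrm{tr}(\hat R^2) d^{-3/2}$, $n = J_0 + J_1 - 2$. The
  exact small-sample constant in the original implementation of this
  method family is not published; ours follows the cited construction and
  may differ in that constant.

KY is affine-invariant and CQ rotation-invariant, so both are unaffected by
the choice of orthonormal ilr basis. SKK standardises by coordinate
variances and is **not** basis-invariant; the package therefore fixes one
documented basis (`helmert_basis()`, row $i \propto (1,\dots,1,-i,0,\dots)$)
everywhere, and records it implicitly in results being reproducible.

## Small-sample behaviour and permutation

At realistic replication ($J = 5$ per group) the asymptotic SKK and CQ
p-values are anti-conservative — our own null simulations
(`mvn_size_study()`) put their empirical size near 0.10–0.13 at nominal
0.05, while KY (where applicable) holds the level. `permutation_pvalue()`
recomputes the statistic under group-label permutations: exhaustively when
$\binom{J_0+J_1}{J_0}$ splits fit in the budget `B` (then
$p = \#\{\text{splits} \ge \text{obs}\}/\#\text{splits}$, observed split
included; with a group-symmetric statistic the attainable minimum at
$5+5$ is $2/252$), otherwise by `B` sampled permutations with
$p = (1 + \#\{\ge\})/(1 + B)$. Ties count as exceedances (conservative).
Permutation restores the nominal level but its minimum p-value at small $J$
may be too large to survive genome-wide adjustment — a real limitation, not
an implementation artifact.

P-values across genes are adjusted with Bonferroni (FWER) or
Benjamini–Hochberg (FDR) via `adjust_pvalues()`; the family is all testable
genes in the comparison.

# The simulator

`simulate_read_pairs()` runs the estimation model forward, so simulated
data match the fitted model by construction: isoform drawn with probability
$\propto \theta_k Z_k$, fragment length from $f$ restricted to
$[\text{read\_len}, l_k]$ with placement weight $l_k - l + 1$, start uniform,
mates projected across junctions to genomic blocks and emitted either
in-memory or as valid coordinate-sorted SAM (`write_sam()`, convertible with
`sam_to_bam()`). Between-sample variation comes from
`sample_usage_vectors()`: ilr-normal draws around the group mean. Defaults
mirror a typical two-group design: $J = 5$ samples per group, mean per-gene
coverage on a 10–110 grid (heterogeneous per-sample coverage supported for
robustness designs), read length 75, discretized-normal fragments
(250, 25). Read count per gene is
$N = \mathrm{round}(\text{coverage} \times \sum_k \theta_k l_k /
(2\,\text{read\_len}))$ — "coverage" is not operationally defined in
general, so this definition is fixed and documented here.

Two deliberate simplifications: (i) the between-sample ilr covariances
default to $0.05\,I$ — the covariances estimated from real placenta data
that motivated the original simulation designs were never published, so
calibration studies here reproduce the *design*, not specific table values;
(ii) reads are emitted pre-aligned and error-free, with the drawn fragment
length conditioned to fit the isoform, whereas estimation uses the
unconditional $Z_k$ — negligible for the shipped toy genes whose isoforms
are much longer than the fragments. Consequently, passing calibration tests
demonstrates internal consistency and correct test calibration under the
stated model; they say nothing about alignment artifacts, positional/GC
bias, annotation errors, or overlapping genes in real data (reads are
assigned independently to every gene whose span contains them, flagged when
shared).

The shipped studies are sized for routine re-running: KY null calibration
at 10,000 replicates, SKK/CQ at 4,000, permutation-SKK at 1,000 datasets
(exhaustive 252 splits each), recovery/power at 200 replicates of a
5-vs-5, coverage-100 design on the built-in cassette-exon gene. These sizes
give binomial standard errors of 0.002–0.022, comfortably inside the
asserted bands.

# Known limitations

* Paired-end data only; no single-end mode.
* No read-level noise class, duplicate handling is off by default, and no
  bias correction.
* SKK p-values depend (mildly) on the ilr basis; the basis is fixed and
  documented rather than user-chosen by default.
* The SKK small-sample constant and the original fragment-length estimator
  details are reconstructed from the cited literature, not copied from the
  original implementation; per-gene p-values may differ slightly from it.
* All asymptotic tests are anti-conservative at very small $J$; prefer the
  permutation mode when the design allows.
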
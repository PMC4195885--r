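# isoUsage

Differential **isoform usage** analysis for paired-end RNA-seq, in R.

A gene with K isoforms spreads its transcript output over them; its *usage*
in a sample is the composition θ = (θ₁, …, θ_K), θ_k ≥ 0, Σθ_k = 1. Changes
in this composition between two groups of samples (tissues, conditions,
genotypes) — as opposed to changes in overall expression — are what this
package detects, for every annotated multi-isoform gene, from BAM
alignments and a GTF annotation.

## Method in brief

**Step 1 — estimation.** For each gene in each sample, every read pair is
scored against every isoform: compatible pairs get an implied fragment
length `l_k^n` (transcript-coordinate span of the pair on isoform k),
incompatible pairs get 0. Under a uniform fragment-placement model with
fragment-length distribution f (estimated per sample from unambiguous
pairs), the per-read weight is `f(l_k^n)/Z_k` with effective length
`Z_k = Σ_l f(l)·max(l_k − l + 1, 0)`. EM maximises the read-mixture
likelihood over the read-origin probabilities p, and usage follows by
inverting the length bias: `θ̂_k ∝ p̂_k / Z_k`.

**Step 2 — testing.** Usage is compositional, so groups are compared in
Aitchison geometry: estimates are mapped to ℝ^(K−1) with an isometric
log-ratio (ilr) transform (zeros replaced by a small ε, default 1e-4;
isoforms zero in all samples dropped) and the two groups are compared with
a multivariate Behrens–Fisher test — SKK (default), CQ, or KY (equal to
Welch's t-test when K = 2) — optionally calibrated by group-label
permutation. P-values are adjusted across genes (Bonferroni or BH).

A read-level simulator (`simulate_read_pairs()`, `run_calibration_study()`)
generates self-consistent alignments from known θ for type-I-error and
power studies, and writes valid SAM for end-to-end pipeline tests.

## Worked example

Simulate a two-group study (5 samples per group, coverage 80) on two
built-in toy genes — `toyA` (2 isoforms, usage shifts 0.80/0.20 →
0.30/0.70 between groups) and `toyB` (3 isoforms, no shift) — with
between-sample biological variation, then run the full pipeline:

```r
library(isoUsage)
genes <- toy_genes()[c("toyA", "toyB")]
fld   <- fld_normal(250, 25)
td    <- tempfile(); dir.create(td)
gtf   <- file.path(td, "toy.gtf"); write_gtf(genes, gtf)

mu <- list(toyA = list(ilr(c(0.80, 0.20)), ilr(c(0.30, 0.70))),
           toyB = list(ilr(c(0.5, 0.3, 0.2)), ilr(c(0.5, 0.3, 0.2))))
bams <- list(character(), character())
for (grp in 0:1) {
  th <- lapply(names(genes), function(gn)
    sample_usage_vectors(mu[[gn]][[grp + 1]], diag(0.04, genes[[gn]]$K - 1),
                         J = 5, seed = 100 + grp + match(gn, names(genes))))
  names(th) <- names(genes)
  for (s in 1:5) {
    sims <- lapply(names(genes), function(gn)
      simulate_read_pairs(genes[[gn]], th[[gn]][[s]], 80, fld,
                          seed = 1000 * grp + 10 * s + match(gn, names(genes))))
    sam <- file.path(td, sprintf("g%d_s%d.sam", grp, s))
    write_sam(sims, genes, sam)
    bams[[grp + 1]] <- c(bams[[grp + 1]], sam_to_bam(sam))
  }
}

m   <- run_manifest(gtf, bams[[1]], bams[[2]], config = list(min_fragments = 200))
out <- run_analysis(m)
out$results[, c("gene_id", "K", "method", "statistic", "p_value", "p_adjusted")]
```

```
  gene_id K method statistic p_value p_adjusted
1    toyA 2    SKK     84.02   0.000      0.000
2    toyB 3    SKK      1.98   0.024      0.024
```

The differentially used gene `toyA` is recovered decisively, and the
estimated group means track the truth closely
(`out$results$group0_usage` → `toyA.1=0.8063;toyA.2=0.1937`, truth
0.80/0.20). Note the null gene `toyB` lands at p = 0.024: the asymptotic
SKK test is anti-conservative with 5 samples per group (its empirical size
is ~0.10–0.13 at nominal 0.05 in the package's own null calibration).
Rerunning the same data with permutation calibration
(`config = list(min_fragments = 200, permute = TRUE, B = 999)`) fixes
exactly this:

```
  gene_id K   method statistic p_value p_adjusted
1    toyA 2 SKK-perm     84.02 0.00794     0.0159
2    toyB 3 SKK-perm      1.98 0.07143     0.0714
```

(0.00794 = 2/252 is the smallest p-value an exhaustive 5-vs-5 permutation
test can produce.)

Lower-level entry points: `estimate_gene_sample_usage()` (one gene, one
sample), `test_gene()` (one gene, two groups of estimates),
`aitchison_distance()` / `ilr()` / `ilr_inverse()` (compositional toolkit),
`mvn_size_study()` (test calibration on multivariate-normal nulls).

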
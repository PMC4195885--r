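#' Empirical fragment-length distribution
#'
#' Builds a discrete pmf over integer fragment lengths from observed
#' unambiguous fragment lengths, optionally truncating extreme quantiles
#' and smoothing with a moving-average kernel.
#'
#' @param lengths Integer vector of observed fragment lengths.
#' @param trunc_quantiles Two quantiles outside which the support is
#'   truncated (default `c(0.001, 0.999)`).
#' @param smooth_window Odd integer half-window for moving-average smoothing
#'   of the pmf; 0 (default) disables smoothing.
#' @return Object of class `fld`: list with integer `support`
#'   (`l_min:l_max`), `pmf` (sums to 1), `cdf`, `mean`.
#' @export
fld_empirical <- function(lengths, trunc_quantiles = c(0.001, 0.999),
                          smooth_window = 0L) {
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) >= 1L, all(lengths >= 1L))
  q <- stats::quantile(lengths, trunc_quantiles, type = 1L)
  lengths <- lengths[lengths >= q[1L] & lengths <= q[2L]]
  support <- min(lengths):max(lengths)
  pmf <- tabulate(lengths - min(lengths) + 1L, length(support))
  pmf <- pmf / sum(pmf)
  if (smooth_window > 0L) {
    k <- rep(1, 2L * smooth_window + 1L)
    pmf <- as.numeric(stats::filter(pmf, k / sum(k), sides = 2L))
    pmf[is.na(pmf)] <- 0
    pmf <- pmf / sum(pmf)
  }
  .fld(support, pmf)
}

#' Discretized normal fragment-length distribution
#'
#' Parametric fallback used when too few unambiguous fragments are
#' available to estimate the distribution empirically.
#'
#' @param mean,sd Mean and standard deviation of the underlying normal.
#' @param width Support half-width in standard deviations (default 4).
#' @return An `fld` object on `max(1, mean - width*sd) : (mean + width*sd)`.
#' @export
fld_normal <- function(mean = 250, sd = 25, width = 4) {
  support <- max(1L, floor(mean - width * sd)):ceiling(mean + width * sd)
  pmf <- stats::dnorm(support, mean, sd)
  .fld(support, pmf / sum(pmf))
}

.fld <- function(support, pmf) {
  stopifnot(all(pmf >= 0), abs(sum(pmf) - 1) < 1e-8)
  structure(list(support = as.integer(support), pmf = pmf,
                 cdf = cumsum(pmf), mean = sum(support * pmf)),
            class = "fld")
}

#' @export
print.fld <- function(x, ...) {
  cat(sprintf("fragment-length distribution on [%d, %d], mean %.1f\n",
              min(x$support), max(x$support), x$mean))
  invisible(x)
}

#' Probability mass of fragment lengths
#'
#' @param fld An `fld` object.
#' @param l Integer vector of lengths.
#' @return `f(l)`, 0 outside the support.
#' @export
fld_prob <- function(fld, l) {
  p <- fld$pmf[match(as.integer(l), fld$support)]
  p[is.na(p)] <- 0
  p
}

#' Unambiguous fragment lengths of a compatibility matrix
#'
#' A read pair is unambiguous when all isoforms it is compatible with imply
#' the same fragment length (e.g. both mates inside one exon shared by all
#' isoforms, or a single-isoform gene); only those pairs inform the
#' fragment-length distribution.
#'
#' @param compat A `compat` object from [build_compatibility()].
#' @return Integer vector of implied lengths, one per unambiguous pair.
#' @export
unambiguous_lengths <- function(compat) {
  lkn <- compat$lkn
  if (!nrow(lkn)) return(integer(0))
  pos_min <- apply(lkn, 1L, function(r) min(r[r > 0L]))
  pos_max <- apply(lkn, 1L, function(r) max(r[r > 0L]))
  pos_min[pos_min == pos_max]
}

#' Estimate the fragment-length distribution from alignments
#'
#' Pools unambiguous fragment lengths across all genes of one sample (a
#' per-sample, genome-wide estimate; per-gene estimates are unstable) and
#' builds an empirical pmf. Falls back to a discretized normal when too few
#' unambiguous fragments are found.
#'
#' @param bam Path to an indexed BAM, or a list of precomputed `compat`
#'   objects (one per gene).
#' @param genes Named list of `GeneModel` objects (ignored when `bam` is a
#'   list of `compat`).
#' @param min_fragments Minimum number of unambiguous fragments required for
#'   the empirical estimate (default 1000).
#' @param fallback_mean,fallback_sd Parameters of the discretized-normal
#'   fallback.
#' @param trunc_quantiles,smooth_window Passed to [fld_empirical()].
#' @param ... Filters passed to [load_read_pairs()].
#' @return An `fld` object.
#' @export
estimate_fld <- function(bam, genes, min_fragments = 1000L,
                         fallback_mean = 250, fallback_sd = 25,
                         trunc_quantiles = c(0.001, 0.999),
                         smooth_window = 0L, ...) {
  compats <- if (is.list(bam) && all(vapply(bam, inherits, TRUE, "compat")))
    bam
  else
    lapply(genes, function(g) build_compatibility(
      load_read_pairs(bam, g, ...), g))
  lens <- unlist(lapply(compats, unambiguous_lengths), use.names = FALSE)
  if (length(lens) < min_fragments) {
    warning("only ", length(lens), " unambiguous fragment(s) (< ",
            min_fragments, "); falling back to discretized normal(",
            fallback_mean, ", ", fallback_sd, "^2)")
    return(fld_normal(fallback_mean, fallback_sd))
  }
  fld_empirical(lens, trunc_quantiles, smooth_window)
}

#' Effective length of an isoform
#'
#' Expected number of valid fragment placements on an isoform of length
#' `l_k` under the fragment-length distribution:
#' \eqn{Z_k = \sum_l f(l) \max(l_k - l + 1, 0)}. Links mixture weights p to
#' usage proportions theta.
#'
#' @param l_k Integer vector of isoform lengths.
#' @param fld An `fld` object.
#' @return Numeric vector of effective lengths (0 when no fragment fits).
#' @export
effective_length <- function(l_k, fld) {
  vapply(l_k, function(L) sum(fld$pmf * pmax(L - fld$support + 1, 0)), 0)
}

#' Per-read likelihood weights
#'
#' Computes the N' x K matrix `a` with
#' \eqn{a_{nk} = f(l_k^n) / Z_k} for compatible entries and 0 otherwise:
#' the probability of the observed alignment given that the pair was drawn
#' from isoform k, under the uniform-placement generative model
#' (fragment length drawn with probability \eqn{f(l)(l_k - l + 1)/Z_k},
#' start position uniform over the \eqn{l_k - l + 1} placements).
#'
#' @param compat A `compat` object.
#' @param fld An `fld` object.
#' @return Numeric matrix (same shape as `compat$lkn`) with attribute
#'   `"Z"` holding the per-isoform effective lengths.
#' @export
compat_weights <- function(compat, fld) {
  Z <- effective_length(compat$iso_lengths, fld)
  lkn <- compat$lkn
  A <- matrix(0, nrow(lkn), ncol(lkn), dimnames = dimnames(lkn))
  pos <- lkn > 0L & lkn <= rep(compat$iso_lengths, each = nrow(lkn))
  if (any(pos)) {
    f <- fld_prob(fld, lkn[pos])
    A[pos] <- f / rep(Z, each = nrow(lkn))[pos]
  }
  attr(A, "Z") <- Z
  A
}

#' Single per-read likelihood term
#'
#' Convenience scalar accessor for one entry of [compat_weights()]:
#' \eqn{a_{nk} = f(l_k^n)/Z_k} when `l_k^n > 0`, else 0.
#'
#' @param n,k Read-pair and isoform indices.
#' @param compat A `compat` object.
#' @param fld An `fld` object.
#' @return A single numeric weight.
#' @export
per_read_term <- function(n, k, compat, fld) {
  unname(compat_weights(compat, fld)[n, k])
}
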
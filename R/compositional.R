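#' Closure: normalise a non-negative vector to the simplex
#'
#' @param v Non-negative numeric vector with positive sum.
#' @return `v / sum(v)` (names preserved).
#' @export
close_comp <- function(v) {
  if (any(v < 0)) stop("negative part")
  s <- sum(v)
  if (s <= 0) stop("cannot close an all-zero vector")
  v / s
}

#' Replace zero parts with a small positive value
#'
#' Zero estimated proportions make log-ratio transforms undefined; zeros
#' are set to `eps` (default 0.0001) and the vector re-closed, so non-zero
#' parts are perturbed only by the re-closure.
#'
#' @param x Composition (non-negative, at least one positive part).
#' @param eps Replacement value (default 1e-4). Larger values (e.g. 0.01)
#'   de-emphasise isoforms with near-zero usage in both groups.
#' @return Strictly positive composition.
#' @export
replace_zeros <- function(x, eps = 1e-4) {
  if (all(x == 0)) stop("all parts zero")
  x[x == 0] <- eps
  close_comp(x)
}

#' Drop isoforms estimated as zero in every sample of both groups
#'
#' An isoform never observed in any sample carries no usage information and
#' is excluded before testing; the remaining parts are re-closed. If only
#' one isoform remains the gene is untestable.
#'
#' @param g0,g1 Lists of per-sample usage compositions (named numeric
#'   vectors of common length K) for groups 0 and 1.
#' @return List with reduced `g0`, `g1`, character `dropped` (isoform
#'   names, possibly empty) and logical `untestable`.
#' @export
drop_all_zero_isoforms <- function(g0, g1) {
  stopifnot(length(g0) >= 2L, length(g1) >= 2L)
  M <- do.call(rbind, c(g0, g1))
  zero_all <- colSums(M > 0) == 0L
  keep <- which(!zero_all)
  red <- function(lst) lapply(lst, function(x) close_comp(x[keep]))
  nm <- colnames(M)
  list(g0 = red(g0), g1 = red(g1),
       dropped = if (is.null(nm)) as.character(which(zero_all)) else
         nm[zero_all],
       untestable = length(keep) < 2L)
}

#' Helmert-type orthonormal ilr basis
#'
#' Rows are orthonormal and orthogonal to the all-ones vector; row i is
#' `(1, ..., 1, -i, 0, ..., 0) / sqrt(i (i + 1))` with i leading ones.
#' This fixed, documented basis makes SKK results reproducible (SKK is the
#' one test here that is not invariant to the basis choice).
#'
#' @param K Number of parts (>= 2).
#' @return `(K-1) x K` matrix `V` with `V %*% t(V) = I`.
#' @export
helmert_basis <- function(K) {
  if (K < 2L) stop("ilr basis requires K >= 2")
  V <- matrix(0, K - 1L, K)
  for (i in seq_len(K - 1L)) {
    V[i, seq_len(i)] <- 1
    V[i, i + 1L] <- -i
    V[i, ] <- V[i, ] / sqrt(i * (i + 1))
  }
  V
}

#' Centered log-ratio transform
#'
#' @param x Strictly positive composition.
#' @return `log(x) - mean(log(x))`.
#' @export
clr <- function(x) {
  if (any(x <= 0))
    stop("clr/ilr require strictly positive parts; see replace_zeros()")
  log(x) - mean(log(x))
}

#' Isometric log-ratio transform and its inverse
#'
#' `ilr` maps the open simplex isometrically onto `R^(K-1)`
#' (Aitchison distance becomes Euclidean distance); `ilr_inverse` maps
#' back. The uniform composition maps to the zero vector.
#'
#' @param x Strictly positive composition (length K).
#' @param basis Orthonormal contrast matrix, default [helmert_basis()].
#' @return `ilr`: numeric vector of length K-1.
#' @export
ilr <- function(x, basis = helmert_basis(length(x))) {
  drop(basis %*% clr(x))
}

#' @rdname ilr
#' @param z Real vector of length K-1.
#' @export
ilr_inverse <- function(z, basis = helmert_basis(length(z) + 1L)) {
  close_comp(exp(drop(crossprod(basis, z))))
}

#' Aitchison distance between two compositions
#'
#' Euclidean norm of the difference of clr vectors; equals the Euclidean
#' distance of the ilr images under any orthonormal basis. Being built on
#' log-ratios, it reflects fold-changes rather than absolute differences.
#'
#' @param x,y Strictly positive compositions of equal length.
#' @return Non-negative scalar distance.
#' @export
aitchison_distance <- function(x, y) {
  if (length(x) != length(y)) stop("compositions of different lengths")
  sqrt(sum((clr(x) - clr(y))^2))
}

#' Compositional mean of a set of usage compositions
#'
#' The mean in Aitchison geometry: the arithmetic mean of the ilr
#' coordinates mapped back to the simplex, equivalently the closed vector
#' of component-wise geometric means.
#'
#' @param samples List of strictly positive compositions of equal length.
#' @return The mean composition (names taken from the first sample).
#' @export
group_mean_usage <- function(samples) {
  stopifnot(length(samples) >= 1L)
  K <- length(samples[[1L]])
  if (K < 2L) return(samples[[1L]])
  B <- helmert_basis(K)
  Zc <- vapply(samples, ilr, numeric(K - 1L), basis = B)
  zbar <- if (K == 2L) mean(Zc) else rowMeans(Zc)
  stats::setNames(ilr_inverse(zbar, B), names(samples[[1L]]))
}
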
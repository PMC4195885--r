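#' Log-likelihood of mixture weights given per-read weights
#'
#' \eqn{\ell(p) = \sum_n \log \sum_k p_k a_{nk}}, the marginal
#' log-likelihood of the observed alignments with the isoform of origin
#' integrated out.
#'
#' @param p Mixture weights on the closed simplex (length K).
#' @param A Per-read weight matrix from [compat_weights()].
#' @return Scalar log-likelihood; `-Inf` triggers an error pointing at
#'   compatibility filtering (a read with zero total weight should have
#'   been dropped upstream).
#' @export
log_likelihood <- function(p, A) {
  stopifnot(length(p) == ncol(A), all(p >= -1e-12),
            abs(sum(p) - 1) < 1e-6)
  s <- drop(A %*% p)
  if (any(s <= 0))
    stop("read with zero likelihood under all isoforms; check ",
         "compatibility filtering / fragment-length support")
  sum(log(s))
}

#' EM maximisation of the read-mixture likelihood
#'
#' Treating each pair's isoform of origin as a latent variable, iterates
#' E-step responsibilities \eqn{w_{nk} = p_k a_{nk} / \sum_j p_j a_{nj}}
#' and M-step \eqn{p_k \leftarrow \frac1{N'} \sum_n w_{nk}} from a uniform
#' start (optionally extra random starts, best likelihood kept). The
#' log-likelihood is non-decreasing across iterations.
#'
#' @param A Per-read weight matrix (N' x K), no all-zero rows.
#' @param tol Convergence tolerance on `max(abs(p_new - p))` (default 1e-6).
#' @param max_iter Maximum EM iterations per start (default 1000).
#' @param extra_starts Number of additional random (Dirichlet(1)) starts
#'   (default 1); guards against ridges caused by near-identical isoforms.
#' @param start_seed Seed for the random starts; the caller's RNG state is
#'   preserved.
#' @return List: `p_hat`, `log_lik`, `n_iter`, `converged`,
#'   `identifiable` (`FALSE` when two isoforms have numerically identical
#'   weight columns, making p non-identifiable).
#' @export
em_fit <- function(A, tol = 1e-6, max_iter = 1000L, extra_starts = 1L,
                   start_seed = 1L) {
  N <- nrow(A); K <- ncol(A)
  stopifnot(N >= 1L, K >= 1L)
  if (any(rowSums(A) <= 0))
    stop("rows with all-zero weight must be removed before em_fit")
  if (K == 1L)
    return(list(p_hat = stats::setNames(1, colnames(A)),
                log_lik = sum(log(A[, 1L])), n_iter = 0L,
                converged = TRUE, identifiable = TRUE))

  identifiable <- TRUE
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K)
    if (max(abs(A[, i] - A[, j])) <= 1e-12 * max(A)) identifiable <- FALSE

  run1 <- function(p) {
    it <- 0L; conv <- FALSE
    repeat {
      W <- t(t(A) * p)
      p_new <- colMeans(W / rowSums(W))
      it <- it + 1L
      if (max(abs(p_new - p)) < tol) { p <- p_new; conv <- TRUE; break }
      p <- p_new
      if (it >= max_iter) break
    }
    list(p = p, ll = log_likelihood(p, A), it = it, conv = conv)
  }

  starts <- list(rep(1 / K, K))
  if (extra_starts > 0L) {
    starts <- c(starts, local({
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(start_seed)
      lapply(seq_len(extra_starts), function(i) {
        g <- stats::rexp(K); g / sum(g)
      })
    }))
  }
  fits <- lapply(starts, run1)
  best <- fits[[which.max(vapply(fits, `[[`, 0, "ll"))]]
  if (!best$conv)
    warning("EM did not converge within ", max_iter,
            " iterations; best iterate returned")
  list(p_hat = stats::setNames(best$p, colnames(A)), log_lik = best$ll,
       n_iter = best$it, converged = best$conv, identifiable = identifiable)
}

#' Convert mixture weights to usage proportions
#'
#' Longer isoforms attract proportionally more fragments, so the fraction
#' of reads p_k overstates the fraction of transcripts theta_k. Inverting
#' the length bias with the effective lengths Z_k:
#' \eqn{\hat\theta_k = (\hat p_k / Z_k) / \sum_j (\hat p_j / Z_j)}.
#'
#' @param p_hat Mixture weights (sums to 1).
#' @param Z Per-isoform effective lengths (see [effective_length()]).
#' @return Usage composition theta-hat (sums to 1).
#' @export
p_to_theta <- function(p_hat, Z) {
  stopifnot(length(p_hat) == length(Z))
  if (all(Z <= 0)) stop("all effective lengths are zero; gene excluded")
  if (any(Z <= 0 & p_hat > 0))
    stop("positive mixture weight on isoform with zero effective length")
  r <- ifelse(p_hat > 0, p_hat / Z, 0)
  stats::setNames(r / sum(r), names(p_hat))
}

#' Estimate a gene's isoform usage in one sample
#'
#' Step one of the two-step analysis: load (or accept) read pairs, build
#' the compatibility matrix, maximise the likelihood by EM and convert the
#' mixture weights to a usage composition.
#'
#' @param reads An indexed BAM path or a [pair_set()] over the gene.
#' @param gene A `GeneModel`.
#' @param fld An `fld` object for the sample.
#' @param sample_id Label recorded in the result.
#' @param min_reads Minimum usable pairs for estimation (default 10;
#'   genes below are flagged `"insufficient_reads"` but still estimated
#'   when at least one pair is usable).
#' @param ... Passed to [em_fit()] (and to [load_read_pairs()] when `reads`
#'   is a path: `min_mapq` etc. must then be set beforehand).
#' @return Object of class `usage_estimate`: `gene_id`, `sample_id`,
#'   `theta_hat`, `p_hat`, `n_reads`, `log_lik`, `n_iter`, `converged`,
#'   `flags` (character vector; `"no_usable_reads"`,
#'   `"insufficient_reads"`, `"non_identifiable"` as applicable).
#' @export
estimate_gene_sample_usage <- function(reads, gene, fld, sample_id = NA,
                                       min_reads = 10L, ...) {
  ps <- if (inherits(reads, "pair_set")) reads else
    load_read_pairs(reads, gene)
  compat <- build_compatibility(ps, gene)
  K <- gene$K
  flags <- character(0)
  empty <- stats::setNames(rep(NA_real_, K), names(gene$isoforms))

  if (K == 1L) {
    return(structure(list(gene_id = gene$gene_id, sample_id = sample_id,
                          theta_hat = stats::setNames(1, names(gene$isoforms)),
                          p_hat = stats::setNames(1, names(gene$isoforms)),
                          n_reads = nrow(compat$lkn), log_lik = NA_real_,
                          n_iter = 0L, converged = TRUE,
                          flags = "single_isoform"),
                     class = "usage_estimate"))
  }
  if (nrow(compat$lkn) == 0L) {
    return(structure(list(gene_id = gene$gene_id, sample_id = sample_id,
                          theta_hat = empty, p_hat = empty, n_reads = 0L,
                          log_lik = NA_real_, n_iter = 0L, converged = FALSE,
                          flags = "no_usable_reads"),
                     class = "usage_estimate"))
  }
  if (nrow(compat$lkn) < min_reads) flags <- c(flags, "insufficient_reads")
  A <- compat_weights(compat, fld)
  Z <- attr(A, "Z")
  keep <- rowSums(A) > 0
  if (!all(keep)) A <- A[keep, , drop = FALSE]
  if (nrow(A) == 0L) {
    return(structure(list(gene_id = gene$gene_id, sample_id = sample_id,
                          theta_hat = empty, p_hat = empty, n_reads = 0L,
                          log_lik = NA_real_, n_iter = 0L, converged = FALSE,
                          flags = "no_usable_reads"),
                     class = "usage_estimate"))
  }
  fit <- em_fit(A, ...)
  if (!fit$identifiable) flags <- c(flags, "non_identifiable")
  theta <- p_to_theta(fit$p_hat, Z)
  structure(list(gene_id = gene$gene_id, sample_id = sample_id,
                 theta_hat = theta, p_hat = fit$p_hat,
                 n_reads = nrow(A), log_lik = fit$log_lik,
                 n_iter = fit$n_iter, converged = fit$converged,
                 flags = flags),
            class = "usage_estimate")
}

#' @export
print.usage_estimate <- function(x, ...) {
  cat("usage_estimate[", x$gene_id, " / ", as.character(x$sample_id),
      "]: n_reads=", x$n_reads, "\n  theta_hat: ",
      paste(sprintf("%s=%.4f", names(x$theta_hat), x$theta_hat),
            collapse = " "),
      if (length(x$flags)) paste0("\n  flags: ",
                                  paste(x$flags, collapse = ",")) else "",
      "\n", sep = "")
  invisible(x)
}
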
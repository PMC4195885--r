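# Two-sample mean tests on ilr coordinates: the multivariate Behrens-Fisher
# problem (unequal, unknown group covariances). X is J0 x d, Y is J1 x d.

.as_group_matrix <- function(M, name) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop(name, ": at least two samples per group required")
  if (!all(is.finite(M))) stop(name, ": non-finite ilr coordinates")
  M
}

.test_result <- function(method, statistic, p_value, df = NA_real_,
                         flags = character(0), gene_id = NA_character_,
                         group_means = NULL) {
  structure(list(gene_id = gene_id, method = method,
                 statistic = statistic, p_value = p_value,
                 p_adjusted = NA_real_, df = df,
                 group_means = group_means, flags = flags),
            class = "iso_test_result")
}

#' @export
print.iso_test_result <- function(x, ...) {
  cat(sprintf("%s test%s: statistic = %.4g, p = %.4g%s\n", x$method,
              if (!is.na(x$gene_id)) paste0(" [", x$gene_id, "]") else "",
              x$statistic, x$p_value,
              if (length(x$flags)) paste0(" (", paste(x$flags,
                                                      collapse = ","), ")")
              else ""))
  invisible(x)
}

#' KY test for equal multivariate means with unequal covariances
#'
#' Hotelling-type statistic \eqn{T^2 = (\bar x - \bar y)' \tilde S^{-1}
#' (\bar x - \bar y)} with \eqn{\tilde S = S_1/J_0 + S_2/J_1}, referred to
#' an F distribution with approximate degrees of freedom estimated from the
#' trace formula of Krishnamoorthy & Yu (2004):
#' \eqn{T^2 (\nu - d + 1)/(\nu d) \sim F(d, \nu - d + 1)}. For d = 1 this
#' reduces exactly to Welch's t-test. Requires `S-tilde` positive definite,
#' hence fewer dimensions than samples per group.
#'
#' @param X,Y Numeric matrices of ilr coordinates (samples x d).
#' @return An object of class `iso_test_result`.
#' @export
ky_test <- function(X, Y) {
  X <- .as_group_matrix(X, "X"); Y <- .as_group_matrix(Y, "Y")
  stopifnot(ncol(X) == ncol(Y))
  d <- ncol(X); n1 <- nrow(X); n2 <- nrow(Y)
  S1 <- stats::cov(X) / n1
  S2 <- stats::cov(Y) / n2
  St <- S1 + S2
  ch <- tryCatch(chol(St), error = function(e) NULL)
  if (is.null(ch) || d >= min(n1, n2))
    return(.test_result("KY", NA_real_, NA_real_,
                        flags = "ky_inapplicable"))
  delta <- colMeans(X) - colMeans(Y)
  Sinv <- chol2inv(ch)
  T2 <- drop(t(delta) %*% Sinv %*% delta)
  tr <- function(M) sum(diag(M))
  A1 <- S1 %*% Sinv; A2 <- S2 %*% Sinv
  denom <- (tr(A1 %*% A1) + tr(A1)^2) / (n1 - 1) +
    (tr(A2 %*% A2) + tr(A2)^2) / (n2 - 1)
  nu <- (d + d^2) / denom
  Fstat <- T2 * (nu - d + 1) / (nu * d)
  p <- stats::pf(Fstat, d, nu - d + 1, lower.tail = FALSE)
  .test_result("KY", T2, p, df = nu)
}

#' Welch's t-test on one-dimensional ilr coordinates
#'
#' For genes with two isoforms the ilr coordinate is a scalar and the
#' group comparison is the classic univariate Behrens-Fisher problem; this
#' wraps [stats::t.test()] under its own method name for transparency (the
#' KY test is algebraically identical at d = 1).
#'
#' @param X,Y One-column matrices (or vectors) of ilr coordinates.
#' @return An `iso_test_result` with the squared t statistic.
#' @export
welch_test <- function(X, Y) {
  x <- drop(as.matrix(X)); y <- drop(as.matrix(Y))
  if (!is.null(dim(x)) || !is.null(dim(y)))
    stop("Welch test applies only to one-dimensional coordinates (K = 2)")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  .test_result("Welch", unname(tt$statistic)^2, tt$p.value,
               df = unname(tt$parameter))
}

#' CQ test for equal multivariate means (Chen & Qin 2010)
#'
#' Sum-of-cross-products statistic that avoids any covariance inversion,
#' so it remains defined when the dimension exceeds the group sizes:
#' \deqn{T = \frac{\sum_{i \ne j} X_i'X_j}{J_0(J_0-1)} +
#'           \frac{\sum_{i \ne j} Y_i'Y_j}{J_1(J_1-1)} -
#'           \frac{2\sum_{i,j} X_i'Y_j}{J_0 J_1}}
#' standardised by the reference's leave-out trace estimators of
#' \eqn{tr(\Sigma_i^2)} and \eqn{tr(\Sigma_1\Sigma_2)}; upper-tail normal
#' p-value. For group sizes below 3 the unbiased trace estimator is
#' undefined and a plug-in `tr(S^2)` is used (flagged).
#'
#' @param X,Y Numeric matrices of ilr coordinates (samples x d).
#' @return An `iso_test_result`.
#' @export
cq_test <- function(X, Y) {
  X <- .as_group_matrix(X, "X"); Y <- .as_group_matrix(Y, "Y")
  stopifnot(ncol(X) == ncol(Y))
  n1 <- nrow(X); n2 <- nrow(Y)
  Gxx <- X %*% t(X); Gyy <- Y %*% t(Y); Gxy <- X %*% t(Y)
  T_stat <- (sum(Gxx) - sum(diag(Gxx))) / (n1 * (n1 - 1)) +
    (sum(Gyy) - sum(diag(Gyy))) / (n2 * (n2 - 1)) -
    2 * sum(Gxy) / (n1 * n2)

  flags <- character(0)
  tr_sigma2 <- function(M) {
    n <- nrow(M)
    if (n < 3L) return(NULL)
    tot <- colSums(M)
    acc <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) if (j != k) {
      mjk <- (tot - M[j, ] - M[k, ]) / (n - 2)
      acc <- acc + sum(M[j, ] * (M[k, ] - mjk)) *
        sum(M[k, ] * (M[j, ] - mjk))
    }
    acc / (n * (n - 1))
  }
  tr1 <- tr_sigma2(X); tr2 <- tr_sigma2(Y)
  if (is.null(tr1)) { tr1 <- sum(stats::cov(X)^2); flags <- "plugin_trace" }
  if (is.null(tr2)) { tr2 <- sum(stats::cov(Y)^2); flags <- "plugin_trace" }
  totX <- colSums(X); totY <- colSums(Y)
  acc <- 0
  for (l in seq_len(n1)) for (k in seq_len(n2)) {
    mx <- (totX - X[l, ]) / (n1 - 1)
    my <- (totY - Y[k, ]) / (n2 - 1)
    acc <- acc + sum(X[l, ] * (Y[k, ] - my)) * sum(Y[k, ] * (X[l, ] - mx))
  }
  tr12 <- acc / (n1 * n2)

  var_hat <- 2 * tr1 / (n1 * (n1 - 1)) + 2 * tr2 / (n2 * (n2 - 1)) +
    4 * tr12 / (n1 * n2)
  var_hat <- max(var_hat, .Machine$double.eps)
  z <- T_stat / sqrt(var_hat)
  res <- .test_result("CQ", z, stats::pnorm(z, lower.tail = FALSE),
                      flags = flags)
  res$raw_statistic <- T_stat
  res
}

#' SKK test for equal multivariate means (Srivastava, Katayama & Koizumi 2013)
#'
#' Diagonally standardised mean-difference statistic
#' \eqn{q = (\bar x - \bar y)' \hat D^{-1} (\bar x - \bar y)} with
#' \eqn{\hat D = diag(S_1/J_0 + S_2/J_1)}; no full covariance inversion, so
#' it applies when d exceeds the group sizes. Standardised as
#' \eqn{z = (q - d) / \sqrt{2 (tr \hat R^2 - d^2/n) c_{d,n}}} with
#' \eqn{\hat R = \hat D^{-1/2} \tilde S \hat D^{-1/2}},
#' \eqn{c_{d,n} = 1 + tr(\hat R^2) d^{-3/2}} (the reference's small-sample
#' correction) and \eqn{n = J_0 + J_1 - 2}; upper-tail normal p-value.
#' At d = 1 the kernel q is exactly the squared Welch t statistic. Unlike
#' KY and CQ, the statistic is not invariant to the ilr basis choice; the
#' fixed [helmert_basis()] is always used by [test_gene()].
#'
#' @param X,Y Numeric matrices of ilr coordinates (samples x d).
#' @return An `iso_test_result`.
#' @export
skk_test <- function(X, Y) {
  X <- .as_group_matrix(X, "X"); Y <- .as_group_matrix(Y, "Y")
  stopifnot(ncol(X) == ncol(Y))
  d <- ncol(X); n1 <- nrow(X); n2 <- nrow(Y)
  St <- stats::cov(X) / n1 + stats::cov(Y) / n2
  Dv <- diag(as.matrix(St))
  flags <- character(0)
  keep <- Dv > 0
  if (!any(keep)) stop("all diagonal variances are zero")
  if (!all(keep)) {
    flags <- "zero_variance_dims_dropped"
    X <- X[, keep, drop = FALSE]; Y <- Y[, keep, drop = FALSE]
    St <- St[keep, keep, drop = FALSE]; Dv <- Dv[keep]
    d <- sum(keep)
  }
  delta <- colMeans(X) - colMeans(Y)
  q <- sum(delta^2 / Dv)
  R <- St / sqrt(outer(Dv, Dv))
  trR2 <- sum(R^2)
  n <- n1 + n2 - 2
  c_dn <- 1 + trR2 / d^1.5
  var_hat <- 2 * (trR2 - d^2 / n) * c_dn
  var_hat <- max(var_hat, .Machine$double.eps)
  z <- (q - d) / sqrt(var_hat)
  .test_result("SKK", z, stats::pnorm(z, lower.tail = FALSE),
               flags = flags)
}

#' Permutation calibration of the SKK / CQ tests
#'
#' The asymptotic SKK and CQ p-values are anti-conservative with few
#' samples per group; permuting group labels restores the nominal type-I
#' error rate. When the number of distinct label splits is at most `B` all
#' splits are enumerated and the p-value is the fraction of splits (the
#' observed one included) whose statistic is at least the observed one;
#' otherwise `B` random permutations are drawn and
#' \eqn{p = (1 + \#\{perm \ge obs\})/(1 + B)}. Ties count as `>=`
#' (conservative).
#'
#' @param method `"SKK"` or `"CQ"`.
#' @param X,Y Numeric matrices of ilr coordinates.
#' @param B Maximum number of permutations (default 10000, minimum 99).
#' @param seed Seed for random permutations (required when sampling; the
#'   caller's RNG state is preserved).
#' @return An `iso_test_result` (statistic = observed standardised
#'   statistic) with flag `"permutation"` and, in exhaustive mode,
#'   `"exhaustive"`.
#' @export
permutation_pvalue <- function(method = c("SKK", "CQ"), X, Y, B = 10000L,
                               seed = NULL) {
  method <- match.arg(method)
  stat_fun <- if (method == "SKK") function(a, b) skk_test(a, b)$statistic
  else function(a, b) cq_test(a, b)$statistic
  X <- .as_group_matrix(X, "X"); Y <- .as_group_matrix(Y, "Y")
  if (B < 99L) stop("B must be at least 99")
  n1 <- nrow(X); n <- n1 + nrow(Y)
  Z <- rbind(X, Y)
  obs <- stat_fun(X, Y)
  nsplit <- choose(n, n1)
  flags <- c("permutation")
  if (nsplit <= B) {
    idx <- utils::combn(n, n1)
    stats_perm <- apply(idx, 2L, function(i)
      stat_fun(Z[i, , drop = FALSE], Z[-i, , drop = FALSE]))
    p <- mean(stats_perm >= obs - 1e-12)
    flags <- c(flags, "exhaustive")
  } else {
    if (is.null(seed)) stop("seed required for sampled permutations")
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    cnt <- 0L
    for (b in seq_len(B)) {
      i <- sample.int(n, n1)
      if (stat_fun(Z[i, , drop = FALSE], Z[-i, , drop = FALSE]) >=
          obs - 1e-12) cnt <- cnt + 1L
    }
    p <- (1 + cnt) / (1 + B)
  }
  .test_result(paste0(method, "-perm"), obs, p, flags = flags)
}

#' Multiple-testing adjustment across genes
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]` (NAs allowed,
#'   propagated).
#' @param method `"bonferroni"` (family-wise error control) or `"BH"`
#'   (Benjamini-Hochberg false-discovery-rate control).
#' @return Adjusted p-values via [stats::p.adjust()].
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = method)
}

#' Test one gene for differential isoform usage
#'
#' Step two of the analysis. Per-sample usage compositions of the two
#' groups are reduced (isoforms zero in every sample dropped), zeros
#' replaced by `eps`, mapped to ilr coordinates under the fixed Helmert
#' basis, and compared with the selected two-sample mean test.
#'
#' @param g0,g1 Lists of per-sample usage estimates for groups 0 and 1:
#'   either `usage_estimate` objects or plain named compositions. At least
#'   two usable samples per group.
#' @param method `"SKK"` (default, the recommended test), `"CQ"`, `"KY"`,
#'   or `"Welch"` (K = 2 only).
#' @param eps Zero-replacement value (default 1e-4).
#' @param permute Calibrate SKK/CQ by permutation (default `FALSE`).
#' @param B,seed Permutation budget and seed (see [permutation_pvalue()]).
#' @param gene_id Label for the result.
#' @return An `iso_test_result` with per-group compositional mean usages
#'   (on the reduced isoform set) and flags (`dropped:` isoforms,
#'   `eps_applied`, `untestable` with NA p-value when fewer than two
#'   isoforms remain).
#' @export
test_gene <- function(g0, g1, method = c("SKK", "CQ", "KY", "Welch"),
                      eps = 1e-4, permute = FALSE, B = 10000L,
                      seed = NULL, gene_id = NA_character_) {
  method <- match.arg(method)
  get_theta <- function(u) if (inherits(u, "usage_estimate")) u$theta_hat
  else u
  usable <- function(lst) Filter(function(x) all(is.finite(x)),
                                 lapply(lst, get_theta))
  t0 <- usable(g0); t1 <- usable(g1)
  if (length(t0) < 2L || length(t1) < 2L)
    stop("at least two usable samples per group required (got ",
         length(t0), " and ", length(t1), ")")
  red <- drop_all_zero_isoforms(t0, t1)
  flags <- character(0)
  if (length(red$dropped))
    flags <- paste0("dropped:", paste(red$dropped, collapse = "+"))
  if (red$untestable)
    return(.test_result(method, NA_real_, NA_real_,
                        flags = c(flags, "untestable"), gene_id = gene_id))
  any_zero <- any(vapply(c(red$g0, red$g1), function(x) any(x == 0), TRUE))
  if (any_zero) flags <- c(flags, "eps_applied")
  c0 <- lapply(red$g0, replace_zeros, eps = eps)
  c1 <- lapply(red$g1, replace_zeros, eps = eps)
  K <- length(c0[[1L]])
  V <- helmert_basis(K)
  X <- t(vapply(c0, ilr, numeric(K - 1L), basis = V))
  Y <- t(vapply(c1, ilr, numeric(K - 1L), basis = V))
  if (K == 2L) { X <- matrix(X, ncol = 1L); Y <- matrix(Y, ncol = 1L) }

  res <- if (permute && method %in% c("SKK", "CQ"))
    permutation_pvalue(method, X, Y, B = B, seed = seed)
  else switch(method,
              SKK = skk_test(X, Y),
              CQ = cq_test(X, Y),
              KY = ky_test(X, Y),
              Welch = {
                if (K != 2L) stop("Welch requires exactly two isoforms")
                welch_test(X, Y)
              })
  res$gene_id <- gene_id
  res$flags <- c(flags, res$flags)
  res$group_means <- list(group0 = group_mean_usage(c0),
                          group1 = group_mean_usage(c1))
  res
}

#' Monte-Carlo size/power of a test on multivariate-normal data
#'
#' Draws `reps` pairs of groups from d-dimensional normals (group 1 mean
#' shifted by `delta`) and records the rejection fraction at level
#' `alpha` — the empirical type-I error rate when `delta = 0`, power
#' otherwise. Used for calibration studies of the asymptotic tests.
#'
#' @param method `"SKK"`, `"CQ"`, `"KY"`, or `"SKK-perm"` / `"CQ-perm"`.
#' @param J0,J1 Group sizes.
#' @param d Dimension (K - 1).
#' @param reps Number of Monte-Carlo replicates.
#' @param alpha Nominal level (default 0.05).
#' @param Sigma0,Sigma1 Group covariances (default identity).
#' @param delta Mean shift vector for group 1 (default zero: null).
#' @param B Permutation budget for the `-perm` methods.
#' @param seed Seed (the caller's RNG is preserved).
#' @return List: `rate` (rejection fraction), `se` (binomial standard
#'   error), `reps`.
#' @export
mvn_size_study <- function(method, J0, J1, d, reps, alpha = 0.05,
                           Sigma0 = diag(d), Sigma1 = diag(d),
                           delta = rep(0, d), B = 999L, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  R0 <- chol(Sigma0); R1 <- chol(Sigma1)
  rej <- 0L
  for (r in seq_len(reps)) {
    X <- matrix(stats::rnorm(J0 * d), J0, d) %*% R0
    Y <- matrix(stats::rnorm(J1 * d), J1, d) %*% R1 +
      matrix(delta, J1, d, byrow = TRUE)
    p <- switch(method,
                SKK = skk_test(X, Y)$p_value,
                CQ = cq_test(X, Y)$p_value,
                KY = ky_test(X, Y)$p_value,
                `SKK-perm` = permutation_pvalue("SKK", X, Y, B = B,
                                                seed = seed + r)$p_value,
                `CQ-perm` = permutation_pvalue("CQ", X, Y, B = B,
                                               seed = seed + r)$p_value,
                stop("unknown method ", method))
    if (!is.na(p) && p < alpha) rej <- rej + 1L
  }
  rate <- rej / reps
  list(rate = rate, se = sqrt(rate * (1 - rate) / reps), reps = reps)
}
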
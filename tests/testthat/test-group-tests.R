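rmat <- function(n, d, shift = 0) matrix(rnorm(n * d) + shift, n, d)

test_that("KY equals Welch's t-test in one dimension", {
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = runif(1))
    ky <- ky_test(matrix(x), matrix(y))
    expect_equal(ky$p_value, t.test(x, y)$p.value, tolerance = 1e-12)
    expect_equal(welch_test(x, y)$p_value, ky$p_value, tolerance = 1e-12)
  }
})

test_that("KY: identical groups give statistic 0 and p = 1", {
  set.seed(42)
  X <- rmat(6, 2)
  ky <- ky_test(X, X)
  expect_equal(ky$statistic, 0)
  expect_equal(ky$p_value, 1)
})

test_that("KY is invariant to the ilr basis (affine invariance)", {
  set.seed(43)
  K <- 4
  V1 <- helmert_basis(K)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  V2 <- Q %*% V1
  comp0 <- lapply(1:6, function(i) close_comp(rexp(K)))
  comp1 <- lapply(1:6, function(i) close_comp(rexp(K) * c(2, 1, 1, 0.5)))
  mk <- function(cs, V) t(vapply(cs, ilr, numeric(K - 1), basis = V))
  p1 <- ky_test(mk(comp0, V1), mk(comp1, V1))$p_value
  p2 <- ky_test(mk(comp0, V2), mk(comp1, V2))$p_value
  expect_equal(p1, p2, tolerance = 1e-9)
  # CQ is invariant to orthonormal rotation of the coordinates
  c1 <- cq_test(mk(comp0, V1), mk(comp1, V1))$p_value
  c2 <- cq_test(mk(comp0, V2), mk(comp1, V2))$p_value
  expect_equal(c1, c2, tolerance = 1e-9)
  # SKK (diagonal standardisation) is documented NOT to be invariant
  s1 <- skk_test(mk(comp0, V1), mk(comp1, V1))$statistic
  s2 <- skk_test(mk(comp0, V2), mk(comp1, V2))$statistic
  expect_false(isTRUE(all.equal(s1, s2, tolerance = 1e-9)))
})

test_that("KY is flagged inapplicable when dimension >= group size", {
  set.seed(44)
  res <- ky_test(rmat(3, 3), rmat(3, 3))
  expect_true("ky_inapplicable" %in% res$flags)
  expect_true(is.na(res$p_value))
})

test_that("CQ statistic matches hand cross-product arithmetic", {
  X <- matrix(c(1, 2), 2, 1); Y <- matrix(c(4, 7), 2, 1)
  # T = sum_{i!=j} XiXj/(n1(n1-1)) + sum YiYj/(n2(n2-1)) - 2 sum XiYj/(n1 n2)
  T_hand <- (1 * 2 + 2 * 1) / (2 * 1) + (4 * 7 + 7 * 4) / (2 * 1) -
    2 * (1 * 4 + 1 * 7 + 2 * 4 + 2 * 7) / (2 * 2)
  cq <- cq_test(X, Y)
  expect_equal(cq$raw_statistic, T_hand, tolerance = 1e-12)
  # the standardised statistic must be positive (groups well separated)
  expect_gt(cq$statistic, 0)
  expect_lt(cq$p_value, 0.5)
  # identical constant groups: T = 0 exactly
  Z <- matrix(1, 3, 2)
  expect_equal(cq_test(Z, Z)$statistic, 0)
})

test_that("CQ rejects strongly for large location shifts", {
  set.seed(45)
  p <- cq_test(rmat(8, 3), rmat(8, 3, shift = 5))$p_value
  expect_lt(p, 1e-6)
})

test_that("SKK kernel reduces to the squared Welch t at d = 1", {
  set.seed(46)
  x <- rnorm(6); y <- rnorm(5, 1)
  St <- var(x) / 6 + var(y) / 5
  q <- (mean(x) - mean(y))^2 / St
  t_w <- unname(t.test(x, y)$statistic)
  expect_equal(q, t_w^2, tolerance = 1e-12)
  # the statistic returned is the standardised z of that kernel
  z <- skk_test(matrix(x), matrix(y))$statistic
  n <- 6 + 5 - 2
  expect_equal(z, (q - 1) / sqrt(2 * (1 - 1 / n) * 2), tolerance = 1e-10)
})

test_that("SKK: identical groups sit at the null centre", {
  set.seed(47)
  X <- rmat(5, 3)
  res <- skk_test(X, X)
  expect_lt(res$statistic, 0)  # q = 0 < d, below the null centre
  expect_gt(res$p_value, 0.5)
})

test_that("permutation p-values: exhaustive enumeration and conventions", {
  set.seed(48)
  X <- rmat(5, 2); Y <- rmat(5, 2, shift = 6)
  res <- permutation_pvalue("SKK", X, Y, B = 999)
  expect_true("exhaustive" %in% res$flags)
  # 252 labelled splits; the observed split and its mirror (the statistic
  # is group-exchange symmetric) are always counted: minimum attainable p
  expect_equal(res$p_value, 2 / choose(10, 5))
  # deterministic in exhaustive mode
  expect_equal(permutation_pvalue("SKK", X, Y, B = 999)$p_value,
               res$p_value)
  # sampled mode: (1 + count)/(1 + B), needs a seed
  Xb <- rmat(8, 2); Yb <- rmat(8, 2)
  expect_error(permutation_pvalue("CQ", Xb, Yb, B = 500), "seed")
  ps <- permutation_pvalue("CQ", Xb, Yb, B = 500, seed = 9)
  expect_gte(ps$p_value, 1 / 501)
  expect_equal(ps$p_value,
               permutation_pvalue("CQ", Xb, Yb, B = 500, seed = 9)$p_value)
  expect_error(permutation_pvalue("SKK", X, Y, B = 50), "at least 99")
})

test_that("multiple-testing adjustment: bonferroni and BH step-up", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.001, 0.5), "bonferroni"), c(0.002, 1))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "pvals")
})

test_that("all tests are invariant to group exchange and sample order", {
  set.seed(49)
  X <- rmat(5, 2); Y <- rmat(6, 2, shift = 1)
  for (f in list(ky_test, cq_test, skk_test)) {
    expect_equal(f(X, Y)$p_value, f(Y, X)$p_value, tolerance = 1e-10)
    expect_equal(f(X, Y)$p_value,
                 f(X[sample(5), , drop = FALSE], Y)$p_value,
                 tolerance = 1e-10)
  }
})

test_that("test_gene runs the full reduction -> ilr -> test pipeline", {
  g0 <- list(c(a = .6, b = .4, c = 0), c(a = .55, b = .45, c = 0),
             c(a = .65, b = .35, c = 0))
  g1 <- list(c(a = .2, b = .8, c = 0), c(a = .25, b = .75, c = 0),
             c(a = .15, b = .85, c = 0))
  res <- test_gene(g0, g1, method = "SKK", gene_id = "gX")
  expect_match(res$flags[1L], "dropped:c")
  expect_named(res$group_means$group0, c("a", "b"))
  expect_lt(res$p_value, 0.05)
  expect_equal(sum(res$group_means$group0), 1)
  # Welch on a 2-isoform gene equals KY
  pW <- test_gene(g0, g1, method = "Welch")$p_value
  pK <- test_gene(g0, g1, method = "KY")$p_value
  expect_equal(pW, pK, tolerance = 1e-10)
  # identical groups: far from significance
  same <- list(c(a = .5, b = .3, c = .2), c(a = .52, b = .28, c = .2),
               c(a = .48, b = .32, c = .2))
  expect_gt(test_gene(same, same, method = "SKK")$p_value, 0.4)
  # reduction to one isoform -> untestable
  g0u <- list(c(a = 1, b = 0), c(a = 1, b = 0))
  expect_true("untestable" %in% test_gene(g0u, g0u)$flags)
  expect_true(is.na(test_gene(g0u, g0u)$p_value))
  expect_error(test_gene(g0[1], g1), "at least two")
})

test_that("usage_estimate objects and plain compositions are accepted", {
  g <- toy_genes()$toyA
  fld <- fld_normal(250, 25)
  mk <- function(theta, seed)
    estimate_gene_sample_usage(
      simulate_read_pairs(g, theta, 60, fld, seed = seed)$pairs, g, fld)
  e0 <- lapply(1:3, function(s) mk(c(0.8, 0.2), s))
  e1 <- lapply(4:6, function(s) mk(c(0.3, 0.7), s))
  res <- test_gene(e0, e1, method = "SKK", gene_id = "toyA")
  expect_lt(res$p_value, 0.05)
  expect_gt(res$group_means$group0[["toyA.1"]],
            res$group_means$group1[["toyA.1"]])
})
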
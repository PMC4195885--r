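test_that("usage draws follow the logistic-normal model", {
  # degenerate covariance: every sample equals the back-transformed mean
  mu <- c(0.4, -0.2)
  draws <- sample_usage_vectors(mu, matrix(0, 2, 2), J = 4, seed = 1)
  for (d in draws) expect_equal(d, ilr_inverse(mu), tolerance = 1e-12)
  # CLT: ilr sample mean close to the target mean
  S <- matrix(c(0.3, 0.1, 0.1, 0.2), 2)
  big <- sample_usage_vectors(mu, S, J = 4000, seed = 2)
  Z <- t(vapply(big, ilr, numeric(2)))
  se <- sqrt(diag(S) / 4000)
  expect_true(all(abs(colMeans(Z) - mu) < 3 * se))
  expect_true(all(vapply(big, function(x) all(x > 0), TRUE)))
  # reproducible given the seed
  expect_identical(sample_usage_vectors(mu, S, J = 3, seed = 7),
                   sample_usage_vectors(mu, S, J = 3, seed = 7))
})

test_that("simulated pairs are self-consistent with their source isoform", {
  fld <- fld_normal(250, 25)
  for (gname in c("toyA", "toyNeg", "toyC")) {
    g <- toy_genes()[[gname]]
    theta <- close_comp(seq_len(g$K))
    sim <- simulate_read_pairs(g, theta, 40, fld, seed = 17)
    lkn <- vapply(g$isoforms, function(iso)
      implied_fragment_length(sim$pairs, iso),
      integer(n_pairs(sim$pairs)))
    src <- match(sim$truth$isoform, names(g$isoforms))
    # implied length on the source isoform equals the drawn fragment length
    expect_equal(lkn[cbind(seq_len(nrow(lkn)), src)], sim$truth$frag_len)
  }
})

test_that("absent isoforms generate no reads and no private junctions", {
  fld <- fld_normal(250, 25)
  g <- toy_genes()$toyA
  # only the skipping isoform expressed: every pair must be compatible
  # with it (no read requires the middle exon)
  sim <- simulate_read_pairs(g, c(0, 1), 60, fld, seed = 23)
  expect_true(all(sim$truth$isoform == "toyA.2"))
  l2 <- implied_fragment_length(sim$pairs, g$isoforms$toyA.2)
  expect_true(all(l2 > 0))
  # single-exon single-isoform gene: each mate is one unsplit block
  s1 <- simulate_read_pairs(toy_genes()$toySingle, 1, 30, fld, seed = 29)
  expect_equal(nrow(s1$pairs$blocks), 2L * n_pairs(s1$pairs))
})

test_that("read depth scales with the requested coverage", {
  fld <- fld_normal(250, 25)
  g <- toy_genes()$toyA
  theta <- c(0.5, 0.5)
  exp_N <- function(cov) round(cov * sum(theta * c(1300, 900)) / (2 * 75))
  for (cov in c(10, 100)) {
    sim <- simulate_read_pairs(g, theta, cov, fld, read_len = 75L, seed = 3)
    expect_equal(n_pairs(sim$pairs), exp_N(cov))
  }
})

test_that("SAM output is valid, deterministic, and round-trips via BAM", {
  fld <- fld_normal(250, 25)
  genes <- toy_genes()[c("toyA", "toyNeg")]
  sims <- lapply(genes, function(g)
    simulate_read_pairs(g, close_comp(rep(1, g$K)), 30, fld,
                        seed = 7 + g$K))
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(sims, genes, f1)
  sims_again <- lapply(genes, function(g)
    simulate_read_pairs(g, close_comp(rep(1, g$K)), 30, fld,
                        seed = 7 + g$K))
  write_sam(sims_again, genes, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical rerun
  bam <- sam_to_bam(f1)
  for (gname in names(genes)) {
    g <- genes[[gname]]
    ps <- load_read_pairs(bam, g)
    expect_equal(n_pairs(ps), n_pairs(sims[[gname]]$pairs))
    # blocks read back from BAM match the emitted blocks exactly
    ord <- order(ps$read_ids)
    got <- ps$blocks
    got$pair <- match(ps$read_ids, sims[[gname]]$pairs$read_ids)[got$pair]
    want <- sims[[gname]]$pairs$blocks
    key <- function(d) do.call(order, d[c("pair", "mate", "start")])
    expect_equal(got[key(got), c("pair", "mate", "start", "end")],
                 want[key(want), c("pair", "mate", "start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("unambiguous fragment lengths reproduce the input distribution", {
  fld <- fld_normal(250, 25)
  g <- toy_genes()$toySingle  # all pairs unambiguous
  sim <- simulate_read_pairs(g, 1, coverage = 6300, fld, seed = 37)
  cm <- build_compatibility(sim$pairs, g)
  lens <- unambiguous_lengths(cm)
  expect_gt(length(lens), 45000)
  ks <- suppressWarnings(ks.test(lens, function(q)
    approx(fld$support, fld$cdf, xout = q, yleft = 0, yright = 1,
           method = "constant")$y))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("isoforms shorter than all fragments are excluded from placement", {
  short <- gene_model("gS", list(
    isoform_model("long", "gS", "chrT", "+", 0, 2000),
    isoform_model("tiny", "gS", "chrT", "+", 0, 120)))
  fld <- fld_normal(250, 25)
  sim <- simulate_read_pairs(short, c(0.5, 0.5), 30, fld, seed = 5)
  expect_equal(attr(sim, "excluded"), "tiny")
  expect_true(all(sim$truth$isoform == "long"))
})

test_that("read-level calibration study returns rates with uncertainty", {
  fld <- fld_normal(250, 25)
  g <- toy_genes()$toyA
  out <- run_calibration_study(g, fld, ilr_mean0 = 0.3,
                               Sigma0 = matrix(0.05), J = 3L,
                               coverage = 30, n_reps = 8L, seed = 61)
  expect_true(out$rate >= 0 && out$rate <= 1)
  expect_lt(out$mean_abs_error, 0.15)
  # heterogeneous per-sample coverage is accepted
  out2 <- run_calibration_study(g, fld, ilr_mean0 = 0.3, J = 5L,
                                coverage = c(30, 50, 70, 90, 110),
                                n_reps = 3L, seed = 62)
  expect_equal(out2$n_reps, 3L)
})
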
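#' Built-in toy gene models
#'
#' Small multi-isoform genes used in examples, tests and calibration
#' studies, all on a synthetic chromosome `chrT`:
#' * `toyA` — 2 isoforms (3 exons; the second isoform skips the middle
#'   exon): the classic cassette-exon gene.
#' * `toyB` — 3 isoforms sharing a first exon with alternative internal
#'   exons.
#' * `toyC` — 5 isoforms over 5 exons with assorted exon subsets.
#' * `toyNeg` — the cassette-exon gene on the minus strand.
#' * `toySingle` — a single-isoform, single-exon gene.
#'
#' @return Named list of `GeneModel` objects.
#' @export
toy_genes <- function() {
  iso <- function(id, g, starts, ends, strand = "+")
    isoform_model(id, g, "chrT", strand, starts, ends)
  list(
    toyA = gene_model("toyA", list(
      iso("toyA.1", "toyA", c(1000, 1600, 2400), c(1400, 2000, 2900)),
      iso("toyA.2", "toyA", c(1000, 2400), c(1400, 2900)))),
    toyB = gene_model("toyB", list(
      iso("toyB.1", "toyB", c(5000, 5800, 6600), c(5500, 6200, 7200)),
      iso("toyB.2", "toyB", c(5000, 6600), c(5500, 7200)),
      iso("toyB.3", "toyB", c(5000, 5800), c(5500, 6400)))),
    toyC = gene_model("toyC", list(
      iso("toyC.1", "toyC", c(10000, 10700, 11500, 12200, 13000),
          c(10500, 11100, 11900, 12700, 13500)),
      iso("toyC.2", "toyC", c(10000, 11500, 13000),
          c(10500, 11900, 13500)),
      iso("toyC.3", "toyC", c(10000, 10700, 13000),
          c(10500, 11100, 13500)),
      iso("toyC.4", "toyC", c(10000, 12200, 13000),
          c(10500, 12700, 13500)),
      iso("toyC.5", "toyC", c(10000, 13000), c(10500, 13600)))),
    toyNeg = gene_model("toyNeg", list(
      iso("toyNeg.1", "toyNeg", c(20000, 20600, 21400),
          c(20400, 21000, 21900), "-"),
      iso("toyNeg.2", "toyNeg", c(20000, 21400), c(20400, 21900), "-"))),
    toySingle = gene_model("toySingle", list(
      iso("toySingle.1", "toySingle", 30000, 31200)))
  )
}

#' Draw per-sample usage compositions from the logistic-normal model
#'
#' The between-sample model of usage variation: each sample's usage
#' composition, after ilr transformation, is an independent draw from a
#' normal distribution on `R^(K-1)` centred at the group's ilr mean.
#'
#' @param ilr_mean Group mean on ilr coordinates (length K-1).
#' @param Sigma Positive semi-definite (K-1) x (K-1) covariance matrix.
#' @param J Number of samples to draw.
#' @param seed Optional seed (caller's RNG preserved when supplied).
#' @param basis ilr basis, default [helmert_basis()].
#' @return List of J strictly positive compositions of length K.
#' @export
sample_usage_vectors <- function(ilr_mean, Sigma, J, seed = NULL,
                                 basis = helmert_basis(length(ilr_mean) + 1L)) {
  d <- length(ilr_mean)
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == d, ncol(Sigma) == d)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  Zm <- MASS::mvrnorm(J, mu = ilr_mean, Sigma = Sigma)
  if (J == 1L) Zm <- matrix(Zm, 1L)
  lapply(seq_len(J), function(j) ilr_inverse(Zm[j, ], basis))
}

#' Simulate paired-end read alignments for one gene in one sample
#'
#' Runs the estimation model forward. The number of pairs is
#' `N = round(coverage * sum(theta * l_k) / (2 * read_len))` (mean
#' per-base depth times the usage-weighted transcript length, divided by
#' the sequenced bases per pair). Each pair draws its isoform from
#' `Categorical(p)` with \eqn{p_k \propto \theta_k Z_k}; its fragment
#' length from `f` restricted to `[read_len, l_k]` with placement weight
#' `l_k - l + 1`; and its start uniformly over the valid placements. Mate
#' intervals are projected across exon junctions to genomic blocks.
#'
#' @param gene A `GeneModel`.
#' @param theta Usage composition over the gene's isoforms (zeros allowed:
#'   absent isoforms produce no reads).
#' @param coverage Mean per-base read coverage.
#' @param fld An `fld` object.
#' @param read_len Read (mate) length in nt (default 75).
#' @param seed Optional seed (caller's RNG preserved when supplied).
#' @param prefix Read-name prefix (default the gene id).
#' @return Object of class `sim_reads`: the [pair_set()] in `pairs` plus a
#'   `truth` data.frame (read_id, isoform, frag_len, tstart) and the
#'   `gene_id`. Isoforms too short for every allowed fragment length are
#'   excluded from placement and recorded in `attr(, "excluded")`.
#' @export
simulate_read_pairs <- function(gene, theta, coverage, fld, read_len = 75L,
                                seed = NULL, prefix = gene$gene_id) {
  stopifnot(length(theta) == gene$K, all(theta >= 0), sum(theta) > 0)
  theta <- theta / sum(theta)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  lens <- vapply(gene$isoforms, `[[`, 1L, "length")
  Z <- effective_length(lens, fld)
  placeable <- vapply(seq_len(gene$K), function(k)
    any(fld$support >= read_len & fld$support <= lens[k] & fld$pmf > 0),
    TRUE)
  excluded <- names(gene$isoforms)[theta > 0 & !placeable]
  w <- theta * Z * placeable
  if (all(w == 0)) stop("no isoform can carry a fragment; check fld support")
  p <- w / sum(w)
  N <- max(1L, as.integer(round(coverage * sum(theta * lens) /
                                  (2 * read_len))))
  ks <- sample.int(gene$K, N, replace = TRUE, prob = p)

  frag <- integer(N); tstart <- integer(N)
  for (k in unique(ks)) {
    sel <- which(ks == k); lk <- lens[k]
    sup_ok <- fld$support >= read_len & fld$support <= lk
    wl <- fld$pmf[sup_ok] * (lk - fld$support[sup_ok] + 1)
    ls <- fld$support[sup_ok][sample.int(sum(sup_ok), length(sel),
                                         replace = TRUE, prob = wl)]
    frag[sel] <- ls
    tstart[sel] <- vapply(ls, function(l)
      sample.int(lk - l + 1L, 1L) - 1L, 1L)
  }

  ids <- sprintf("%s_p%06d", prefix, seq_len(N))
  b1 <- vector("list", N); b2 <- vector("list", N)
  for (n in seq_len(N)) {
    iso <- gene$isoforms[[ks[n]]]
    a <- tstart[n]; l <- frag[n]
    b1[[n]] <- .transcript_to_blocks(iso, a, a + read_len)
    b2[[n]] <- .transcript_to_blocks(iso, a + l - read_len, a + l)
  }
  n1 <- vapply(b1, nrow, 1L); n2 <- vapply(b2, nrow, 1L)
  M1 <- do.call(rbind, b1); M2 <- do.call(rbind, b2)
  blocks <- data.frame(
    pair = c(rep(seq_len(N), n1), rep(seq_len(N), n2)),
    mate = rep(c(1L, 2L), c(sum(n1), sum(n2))),
    start = c(M1[, 1L], M2[, 1L]),
    end = c(M1[, 2L], M2[, 2L]))
  ps <- pair_set(ids, blocks, gene$chrom)
  structure(list(pairs = ps, gene_id = gene$gene_id,
                 truth = data.frame(read_id = ids,
                                    isoform = names(gene$isoforms)[ks],
                                    frag_len = frag, tstart = tstart)),
            class = "sim_reads", excluded = excluded)
}

#' Render simulated read pairs as SAM text
#'
#' Produces a valid coordinate-sorted SAM file (header with `@SQ` lines,
#' proper-pair FLAGs, `N` CIGAR operations across introns) that round-trips
#' through `Rsamtools::asBam()` for pipeline use. Output is deterministic:
#' the same simulated object always renders byte-identically.
#'
#' @param sims A `sim_reads` object or list of them (one chromosome).
#' @param genes Named list of `GeneModel`s used, for the `@SQ` header.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sims, genes, path) {
  if (inherits(sims, "sim_reads")) sims <- list(sims)
  chroms <- unique(vapply(genes, `[[`, "", "chrom"))
  sq <- vapply(chroms, function(ch) {
    ln <- max(vapply(genes, function(g)
      if (g$chrom == ch) g$span[2L] else 0L, 1L)) + 1000L
    sprintf("@SQ\tSN:%s\tLN:%d", ch, ln)
  }, "")
  rec <- list()
  for (s in sims) {
    b <- s$pairs$blocks
    per_mate <- function(mate) {
      bm <- b[b$mate == mate, , drop = FALSE]
      sp <- split(bm, bm$pair)
      t(vapply(sp, function(d) {
        d <- d[order(d$start), , drop = FALSE]
        gaps <- if (nrow(d) > 1L) d$start[-1L] - d$end[-nrow(d)] else
          integer(0)
        cig <- paste0(d$end[1L] - d$start[1L], "M")
        if (length(gaps))
          cig <- paste0(cig, paste0(gaps, "N",
                                    d$end[-1L] - d$start[-1L], "M",
                                    collapse = ""))
        c(pos = d$start[1L], end = max(d$end), cigar = cig)
      }, c(pos = "", end = "", cigar = "")))
    }
    m1 <- per_mate(1L); m2 <- per_mate(2L)
    stopifnot(nrow(m1) == nrow(m2))
    n <- length(s$pairs$read_ids)
    ord <- order(as.integer(rownames(m1)))
    m1 <- m1[ord, , drop = FALSE]; m2 <- m2[ord, , drop = FALSE]
    p1 <- as.integer(m1[, "pos"]); p2 <- as.integer(m2[, "pos"])
    e1 <- as.integer(m1[, "end"]); e2 <- as.integer(m2[, "end"])
    tlen <- pmax(e1, e2) - pmin(p1, p2)
    ids <- s$pairs$read_ids
    chrom <- s$pairs$chrom
    rec[[length(rec) + 1L]] <- data.frame(
      qname = rep(ids, 2L),
      flag = rep(c(99L, 147L), each = n),
      pos = c(p1, p2) + 1L,
      cigar = c(m1[, "cigar"], m2[, "cigar"]),
      pnext = c(p2, p1) + 1L,
      tlen = c(tlen, -tlen),
      chrom = chrom)
  }
  rec <- do.call(rbind, rec)
  rec <- rec[order(rec$chrom, rec$pos, rec$qname, rec$flag), , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
                  rec$qname, rec$flag, rec$chrom, rec$pos, rec$cigar,
                  rec$pnext, rec$tlen)
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", sq, body), path)
  invisible(path)
}

#' Convert SAM text to a sorted, indexed BAM
#'
#' Thin wrapper over `Rsamtools::asBam()`/`sortBam()`/`indexBam()` used by
#' tests and simulation studies to feed SAM fixtures into the BAM-based
#' pipeline.
#'
#' @param sam_path Input SAM path.
#' @param bam_prefix Output path without the `.bam` extension (defaults to
#'   the SAM path minus its extension).
#' @return Path to the indexed BAM.
#' @export
sam_to_bam <- function(sam_path, bam_prefix = sub("\\.sam$", "", sam_path)) {
  tmp <- Rsamtools::asBam(sam_path, paste0(bam_prefix, "_unsorted"),
                          overwrite = TRUE, indexDestination = FALSE)
  out <- Rsamtools::sortBam(tmp, bam_prefix)
  Rsamtools::indexBam(out)
  unlink(tmp)
  out
}

#' Empirical size / power of the full read-level pipeline
#'
#' For each replicate, draws group usage compositions from the
#' logistic-normal model, simulates reads for every sample, re-estimates
#' usage with the EM step, runs the selected group test, and records
#' rejection at level `alpha` — type-I error when the two ilr means are
#' equal, power otherwise.
#'
#' @param gene A `GeneModel`.
#' @param fld An `fld` object.
#' @param ilr_mean0 Group-0 mean on ilr coordinates.
#' @param ilr_mean1 Group-1 mean (default `ilr_mean0`: a null study).
#' @param Sigma0,Sigma1 Between-sample ilr covariances (default 0.05 I, a
#'   moderate biological-replicate spread).
#' @param J Samples per group (default 5, as in a typical two-group
#'   design with five replicates each).
#' @param coverage Mean per-base coverage; a scalar, or a vector of length
#'   J recycled across samples for heterogeneous-coverage designs
#'   (e.g. `c(30, 50, 70, 90, 110)`).
#' @param n_reps Number of replicates.
#' @param method Group test (default `"SKK"`).
#' @param alpha Nominal level (default 0.05).
#' @param read_len Read length (default 75).
#' @param eps Zero-replacement value.
#' @param seed Seed (required; every replicate derives from it).
#' @return List: `rate`, `se` (binomial standard error), `n_reps`,
#'   `mean_abs_error` (mean absolute per-component estimation error of
#'   theta over all samples), `n_untestable`.
#' @export
run_calibration_study <- function(gene, fld, ilr_mean0, ilr_mean1 = NULL,
                                  Sigma0 = NULL, Sigma1 = NULL, J = 5L,
                                  coverage = 100, n_reps = 100L,
                                  method = "SKK", alpha = 0.05,
                                  read_len = 75L, eps = 1e-4, seed) {
  d <- length(ilr_mean0)
  stopifnot(d == gene$K - 1L)
  if (is.null(ilr_mean1)) ilr_mean1 <- ilr_mean0
  if (is.null(Sigma0)) Sigma0 <- diag(0.05, d)
  if (is.null(Sigma1)) Sigma1 <- Sigma0
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  cov_vec <- rep_len(coverage, J)
  rej <- 0L; ntest <- 0L; nuntest <- 0L; abs_err <- c()
  for (r in seq_len(n_reps)) {
    th0 <- sample_usage_vectors(ilr_mean0, Sigma0, J)
    th1 <- sample_usage_vectors(ilr_mean1, Sigma1, J)
    est <- function(th, grp) lapply(seq_len(J), function(j) {
      sim <- simulate_read_pairs(gene, th[[j]], cov_vec[j], fld,
                                 read_len = read_len)
      e <- estimate_gene_sample_usage(sim$pairs, gene, fld,
                                      sample_id = paste0(grp, j))
      abs_err <<- c(abs_err, mean(abs(e$theta_hat - th[[j]])))
      e
    })
    res <- test_gene(est(th0, "g0s"), est(th1, "g1s"), method = method,
                     eps = eps, gene_id = gene$gene_id)
    if (is.na(res$p_value)) { nuntest <- nuntest + 1L; next }
    ntest <- ntest + 1L
    if (res$p_value < alpha) rej <- rej + 1L
  }
  rate <- if (ntest) rej / ntest else NA_real_
  list(rate = rate,
       se = if (ntest) sqrt(rate * (1 - rate) / ntest) else NA_real_,
       n_reps = n_reps, mean_abs_error = mean(abs_err),
       n_untestable = nuntest)
}
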
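# toyA: exons iso1 [1000,1400)+[1600,2000)+[2400,2900), iso2 skips the
# middle exon. Lengths 1300 / 900.

test_that("implied fragment length: single-exon and junction cases", {
  g <- toy_genes()$toyA
  iso1 <- g$isoforms$toyA.1; iso2 <- g$isoforms$toyA.2
  # both mates inside one 500-nt exon, outer genomic span 300
  ps <- one_pair(simple_pair_blocks(2400, 300))
  expect_equal(implied_fragment_length(ps, iso1), 300L)
  expect_equal(implied_fragment_length(ps, iso2), 300L)
  # mate straddling the junction into the middle exon (absent from iso2)
  straddle <- data.frame(mate = c(1L, 2L),
                         start = c(1380, 1700), end = c(1420, 1750))
  # mate1 spans 1380-1420 without a split: incompatible with both
  # (iso1 has an intron at 1400; iso2 too)
  expect_equal(implied_fragment_length(one_pair(straddle), iso1), 0L)
  expect_equal(implied_fragment_length(one_pair(straddle), iso2), 0L)
  # correctly split mate across the iso1 junction: compatible with iso1 only
  split_pair <- data.frame(mate = c(1L, 1L, 2L),
                           start = c(1380, 1600, 1700),
                           end = c(1400, 1620, 1750))
  expect_equal(implied_fragment_length(one_pair(split_pair), iso1), 170L)
  expect_equal(implied_fragment_length(one_pair(split_pair), iso2), 0L)
})

test_that("unsplit mate across a skipped exon matches only the skipper", {
  g <- toy_genes()$toyA
  # pair spanning from exon 1 into exon 3 with no blocks in the middle exon
  pr <- data.frame(mate = c(1L, 2L), start = c(1300, 2500),
                   end = c(1350, 2550))
  # both-mates-in-exons case: compatible with both isoforms, but implied
  # lengths differ (middle exon counts only for iso1)
  # exonic distance 1300..2550: rest of exon 1 + exon 2 (iso1 only) + into
  # exon 3
  expect_equal(implied_fragment_length(one_pair(pr), g$isoforms$toyA.1),
               (1400 - 1300) + 400 + (2550 - 2400))  # 650
  expect_equal(implied_fragment_length(one_pair(pr), g$isoforms$toyA.2),
               (1400 - 1300) + (2550 - 2400))        # 250
})

test_that("implied fragment length agrees with brute-force oracle", {
  genes <- toy_genes()
  set.seed(11)
  for (gname in c("toyA", "toyNeg")) {
    g <- genes[[gname]]
    for (iso_src in g$isoforms) {
      for (rep in 1:15) {
        l <- sample(120:260, 1L)
        a <- sample(0:(iso_src$length - l), 1L)
        rl <- 50L
        bm <- base_map(iso_src)
        b1 <- positions_to_blocks(bm[(a + 1L):(a + rl)])
        b2 <- positions_to_blocks(bm[(a + l - rl + 1L):(a + l)])
        bl <- data.frame(mate = rep(c(1L, 2L), c(nrow(b1), nrow(b2))),
                         start = c(b1[, 1L], b2[, 1L]),
                         end = c(b1[, 2L], b2[, 2L]))
        ps <- one_pair(bl)
        for (iso_tgt in g$isoforms) {
          expect_equal(implied_fragment_length(ps, iso_tgt),
                       oracle_implied_length(bl, iso_tgt),
                       info = paste(gname, iso_src$isoform_id,
                                    iso_tgt$isoform_id, rep))
        }
      }
    }
  }
})

test_that("implied fragment length is invariant under mate swap", {
  g <- toy_genes()$toyA
  bl <- data.frame(mate = c(1L, 1L, 2L),
                   start = c(1380, 1600, 1700), end = c(1400, 1620, 1750))
  swapped <- bl; swapped$mate <- 3L - swapped$mate
  for (iso in g$isoforms)
    expect_equal(implied_fragment_length(one_pair(bl), iso),
                 implied_fragment_length(one_pair(swapped), iso))
})

test_that("compatibility matrix: identical isoforms give identical columns", {
  iso1 <- isoform_model("a", "g", "chrT", "+", c(0, 600), c(400, 1000))
  iso2 <- isoform_model("b", "g", "chrT", "+", c(0, 600), c(400, 1000))
  g <- gene_model("g", list(iso1, iso2))
  set.seed(3)
  bl <- do.call(rbind, lapply(1:10, function(i) {
    d <- simple_pair_blocks(sample(0:100, 1), 250)
    d$pair <- i; d
  }))
  cm <- build_compatibility(pair_set(paste0("p", 1:10), bl, "chrT"), g)
  expect_equal(cm$lkn[, 1L], cm$lkn[, 2L])
  expect_true(all(cm$lkn[, 1L] > 0))
})

test_that("unassignable pairs are dropped and counted", {
  g <- toy_genes()$toyA
  bl <- rbind(
    cbind(pair = 1L, simple_pair_blocks(2400, 300)),     # both isoforms
    cbind(pair = 2L, data.frame(mate = c(1L, 2L),        # intronic: neither
                                start = c(2000, 2150), end = c(2050, 2200))),
    cbind(pair = 3L, data.frame(mate = c(1L, 1L, 2L),    # iso1 only
                                start = c(1380, 1600, 1700),
                                end = c(1400, 1620, 1750))))
  cm <- build_compatibility(pair_set(paste0("p", 1:3), bl, "chrT"), g)
  expect_equal(nrow(cm$lkn), 2L)
  expect_equal(cm$n_unassignable, 1L)
  expect_equal(unname(cm$lkn[2L, ]), c(170L, 0L))
})

test_that("load_read_pairs filters and joins mates from BAM", {
  g <- toy_genes()$toyA
  sam <- tempfile(fileext = ".sam")
  rec <- c(
    # proper pair fully inside exon 3 (pos 2401.., span 300)
    "ok1\t99\tchrT\t2401\t60\t50M\t=\t2651\t300\t*\t*",
    "ok1\t147\tchrT\t2651\t60\t50M\t=\t2401\t-300\t*\t*",
    # mate2 on another chromosome -> not a proper pair, excluded
    "bad1\t97\tchrT\t2451\t60\t50M\tchrU\t100\t0\t*\t*")
  write_sam_fixture(sam, rec,
                    sq = c("@SQ\tSN:chrT\tLN:40000", "@SQ\tSN:chrU\tLN:1000"))
  bam <- sam_to_bam(sam)
  ps <- load_read_pairs(bam, g)
  expect_equal(n_pairs(ps), 1L)
  expect_equal(ps$read_ids, "ok1")
  expect_equal(ps$n_excluded, 1L)
  expect_equal(implied_fragment_length(ps, g$isoforms$toyA.1), 300L)
  # empty region
  expect_equal(n_pairs(load_read_pairs(bam, toy_genes()$toyB)), 0L)
  # missing index
  noidx <- tempfile(fileext = ".bam")
  file.copy(bam, noidx)
  expect_error(load_read_pairs(noidx, g), "index")
})

test_that("merging technical replicates pools pairs and suffixes clashes", {
  bl <- simple_pair_blocks(2400, 300); bl$pair <- 1L
  p1 <- pair_set("r1", bl, "chrT")
  p2 <- pair_set("r1", bl, "chrT")  # same read name
  expect_warning(m <- merge_read_pairs(list(p1, p2)), "suffix")
  expect_equal(n_pairs(m), 2L)
  expect_equal(anyDuplicated(m$read_ids), 0L)
  expect_identical(merge_read_pairs(list(p1)), p1)
})
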
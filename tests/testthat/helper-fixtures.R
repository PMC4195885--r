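# Shared fixtures and independent oracles for the test suite.

# --- independent per-base coordinate map -----------------------------------
# Genomic position of every transcript offset (genomic-forward order),
# built by brute enumeration; independent of the package's projection code.
base_map <- function(iso) {
  unlist(Map(function(s, e) s:(e - 1L), iso$starts, iso$ends))
}

# Split a sorted vector of genomic positions into (start, end) blocks.
positions_to_blocks <- function(pos) {
  br <- c(0L, which(diff(pos) != 1L), length(pos))
  t(vapply(seq_len(length(br) - 1L), function(i) {
    p <- pos[(br[i] + 1L):br[i + 1L]]
    c(min(p), max(p) + 1L)
  }, c(1L, 1L)))
}

# Brute-force implied fragment length oracle: try every contiguous
# transcript placement of each mate and check block-by-block concordance.
oracle_implied_length <- function(blocks_df, iso) {
  bm <- base_map(iso)
  mate_range <- function(mate) {
    d <- blocks_df[blocks_df$mate == mate, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    obs <- cbind(d$start, d$end)
    w <- sum(d$end - d$start)
    if (w > iso$length) return(NULL)
    for (a in 0:(iso$length - w)) {
      cand <- positions_to_blocks(bm[(a + 1L):(a + w)])
      if (nrow(cand) == nrow(obs) && all(cand == obs))
        return(c(a, a + w))
    }
    NULL
  }
  r1 <- mate_range(1L); r2 <- mate_range(2L)
  if (is.null(r1) || is.null(r2)) return(0L)
  max(r1[2L], r2[2L]) - min(r1[1L], r2[1L])
}

# Single-pair pair_set from a blocks data.frame (mate/start/end columns).
one_pair <- function(blocks_df, chrom = "chrT", id = "p1") {
  blocks_df$pair <- 1L
  pair_set(id, blocks_df, chrom)
}

# Blocks of a simple unspliced pair: two mates of length rl with outer
# genomic span `span`, leftmost genomic position `left`.
simple_pair_blocks <- function(left, span, rl = 50L) {
  data.frame(mate = c(1L, 2L),
             start = c(left, left + span - rl),
             end = c(left + rl, left + span))
}

# Grid-search maximiser of the 2-isoform mixture likelihood (EM oracle).
grid_mle_p1 <- function(A, step = 1e-4) {
  g <- seq(step, 1 - step, by = step)
  ll <- vapply(g, function(p1) sum(log(A %*% c(p1, 1 - p1))), 0)
  g[which.max(ll)]
}

# Deterministic SAM fixture writer for load_read_pairs tests.
write_sam_fixture <- function(path, records,
                              sq = "@SQ\tSN:chrT\tLN:40000") {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", sq, records), path)
}
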
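#' Build a read-pair set from explicit alignment blocks
#'
#' The internal container for paired-end alignments over a gene region: a
#' long table of aligned blocks (split at N CIGAR operations), two mates per
#' pair. Used both by [load_read_pairs()] and by the simulator, and consumed
#' by [build_compatibility()].
#'
#' @param read_ids Character vector, one id per pair.
#' @param blocks `data.frame` with integer columns `pair` (1-based index into
#'   `read_ids`), `mate` (1 or 2), `start`, `end` (0-based half-open genomic).
#' @param chrom Chromosome name shared by all blocks.
#' @param n_excluded Count of alignments in the region that were dropped
#'   (unpaired, improper, filtered).
#' @return Object of class `pair_set`.
#' @export
pair_set <- function(read_ids, blocks, chrom, n_excluded = 0L) {
  stopifnot(is.data.frame(blocks),
            all(c("pair", "mate", "start", "end") %in% names(blocks)))
  blocks <- blocks[order(blocks$pair, blocks$mate, blocks$start), ,
                   drop = FALSE]
  if (any(blocks$start >= blocks$end)) stop("empty alignment block")
  structure(list(read_ids = read_ids, blocks = blocks, chrom = chrom,
                 n_excluded = as.integer(n_excluded)),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat("pair_set:", length(x$read_ids), "read pair(s) on", x$chrom,
      "|", x$n_excluded, "excluded\n")
  invisible(x)
}

#' Number of read pairs in a pair set
#' @param x A `pair_set`.
#' @export
n_pairs <- function(x) length(x$read_ids)

#' Load paired-end alignments over a gene from an indexed BAM
#'
#' Fetches properly-paired primary alignments whose two mates both overlap
#' the gene span, joins mates by read name, and splits each mate into
#' aligned blocks at N CIGAR operations.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param gene A `GeneModel`.
#' @param min_mapq Minimum mapping quality (default 0).
#' @param proper_only Keep only proper pairs (default `TRUE`).
#' @param dedup Drop duplicate-flagged alignments (default `FALSE`; raw
#'   counts are used unless the caller opts in).
#' @return A [pair_set()]; `n_excluded` counts region records not usable as
#'   a pair (unpaired within region, filtered, mate elsewhere).
#' @export
load_read_pairs <- function(bam, gene, min_mapq = 0L, proper_only = TRUE,
                            dedup = FALSE) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for ", bam,
         "; sort and index the file first")
  which <- GenomicRanges::GRanges(gene$chrom,
                                  IRanges::IRanges(gene$span[1L] + 1L,
                                                   gene$span[2L]))
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE,
    isProperPair = if (proper_only) TRUE else NA,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (dedup) FALSE else NA)
  param <- Rsamtools::ScanBamParam(which = which, flag = flag,
                                   mapqFilter = min_mapq)
  ga <- GenomicAlignments::readGAlignmentPairs(bam, param = param,
                                               use.names = TRUE)
  n_in_region <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(which = which))$records

  if (length(ga)) {
    # both mates must overlap the gene span
    f <- GenomicAlignments::first(ga); l <- GenomicAlignments::last(ga)
    keep <- IRanges::overlapsAny(GenomicRanges::granges(f), which) &
      IRanges::overlapsAny(GenomicRanges::granges(l), which)
    ga <- ga[keep]
  }
  if (!length(ga)) {
    return(pair_set(character(0),
                    data.frame(pair = integer(0), mate = integer(0),
                               start = integer(0), end = integer(0)),
                    gene$chrom, n_excluded = n_in_region))
  }
  .mate_blocks <- function(aln, mate) {
    bl <- GenomicAlignments::grglist(aln)  # per-read block GRangesList
    n <- S4Vectors::elementNROWS(bl)
    flat <- unlist(bl, use.names = FALSE)
    data.frame(pair = rep(seq_along(aln), n), mate = mate,
               start = GenomicRanges::start(flat) - 1L,
               end = GenomicRanges::end(flat))
  }
  blocks <- rbind(.mate_blocks(GenomicAlignments::first(ga), 1L),
                  .mate_blocks(GenomicAlignments::last(ga), 2L))
  pair_set(names(ga), blocks, gene$chrom,
           n_excluded = max(0L, n_in_region - 2L * length(ga)))
}

# Core projection: implied fragment lengths of every pair in `ps` on one
# isoform. A pair is compatible iff every aligned block of both mates lies
# inside a single exon and consecutive blocks of a mate are adjacent in
# transcript coordinates (block edges coincide with the isoform's splice
# junctions). Returns integer vector of l_k^n, 0 = incompatible.
.implied_lengths_iso <- function(ps, iso) {
  np <- length(ps$read_ids)
  if (np == 0L) return(integer(0))
  b <- ps$blocks
  idx <- findInterval(b$start, iso$starts)
  inexon <- idx >= 1L & b$start >= iso$starts[pmax(idx, 1L)] &
    b$end <= iso$ends[pmax(idx, 1L)]
  idx1 <- pmax(idx, 1L)
  ts <- iso$cum[idx1] + (b$start - iso$starts[idx1])  # fwd transcript start
  te <- ts + (b$end - b$start)                         # fwd transcript end
  n <- nrow(b)
  same <- c(FALSE, b$pair[-1L] == b$pair[-n] & b$mate[-1L] == b$mate[-n])
  adjacent <- !same | (ts == c(0L, te[-n]))
  bad_any <- rowsum(as.integer(!inexon | !adjacent), b$pair,
                    reorder = TRUE) > 0L
  pair_levels <- as.integer(rownames(bad_any))
  tmin <- tapply(ifelse(inexon, ts, NA_integer_), b$pair, min)
  tmax <- tapply(ifelse(inexon, te, NA_integer_), b$pair, max)
  lkn <- integer(np)
  ok <- !bad_any[, 1L]
  lkn[pair_levels[ok]] <- as.integer(tmax[ok] - tmin[ok])
  lkn
}

#' Implied fragment length of one read pair on one isoform
#'
#' The transcript-coordinate distance from the 5'-most base of the leftmost
#' mate to the 3'-most base of the rightmost mate, inclusive, if the pair is
#' compatible with the isoform (all aligned blocks map contiguously onto its
#' spliced sequence); 0 otherwise. Symmetric in the two mates and in strand.
#'
#' @param ps A single-pair [pair_set()] (or one with several pairs, in which
#'   case the vector of lengths is returned).
#' @param iso An `IsoformModel` on the same chromosome.
#' @return Integer vector l_k^n, one per pair; 0 = incompatible.
#' @export
implied_fragment_length <- function(ps, iso) {
  if (!identical(ps$chrom, iso$chrom))
    stop("pair set and isoform are on different chromosomes")
  .implied_lengths_iso(ps, iso)
}

#' Per-gene compatibility matrix of implied fragment lengths
#'
#' @param ps A [pair_set()] over the gene region.
#' @param gene A `GeneModel`.
#' @return Object of class `compat`: list with `gene_id`, `read_ids`
#'   (pairs with at least one compatible isoform), `lkn` (N' x K integer
#'   matrix of implied fragment lengths, 0 = incompatible), `iso_lengths`,
#'   `n_unassignable` (pairs compatible with no isoform, dropped). `NULL`
#'   with a "no usable reads" message attribute is never returned; callers
#'   check `nrow(lkn) == 0`.
#' @export
build_compatibility <- function(ps, gene) {
  K <- gene$K
  lkn <- vapply(gene$isoforms, function(iso) .implied_lengths_iso(ps, iso),
                integer(length(ps$read_ids)))
  if (length(ps$read_ids) == 1L) lkn <- matrix(lkn, nrow = 1L)
  if (length(ps$read_ids) == 0L) lkn <- matrix(integer(0), 0L, K)
  colnames(lkn) <- names(gene$isoforms)
  usable <- rowSums(lkn > 0L) > 0L
  structure(list(gene_id = gene$gene_id,
                 read_ids = ps$read_ids[usable],
                 lkn = lkn[usable, , drop = FALSE],
                 iso_lengths = vapply(gene$isoforms, `[[`, 1L, "length"),
                 n_unassignable = sum(!usable)),
            class = "compat")
}

#' @export
print.compat <- function(x, ...) {
  cat("compat[", x$gene_id, "]: ", nrow(x$lkn), " pair(s) x ",
      ncol(x$lkn), " isoform(s); ", x$n_unassignable, " unassignable\n",
      sep = "")
  invisible(x)
}

#' Pool read pairs, e.g. technical replicates of one biological replicate
#'
#' Concatenates pair sets; read ids that collide across sets are
#' disambiguated with a `/techN` suffix (with a warning).
#'
#' @param ps_list List of [pair_set()] objects on one chromosome.
#' @return A single pooled `pair_set`.
#' @export
merge_read_pairs <- function(ps_list) {
  stopifnot(length(ps_list) >= 1L)
  if (length(ps_list) == 1L) return(ps_list[[1L]])
  chrom <- unique(vapply(ps_list, `[[`, "", "chrom"))
  if (length(chrom) != 1L) stop("pair sets on different chromosomes")
  ids <- character(0); blocks <- list(); off <- 0L; clash <- FALSE
  for (i in seq_along(ps_list)) {
    p <- ps_list[[i]]
    id_i <- p$read_ids
    dup <- id_i %in% ids
    if (any(dup)) { clash <- TRUE; id_i[dup] <- paste0(id_i[dup], "/tech", i) }
    b <- p$blocks; b$pair <- b$pair + off
    ids <- c(ids, id_i); blocks[[i]] <- b; off <- off + length(p$read_ids)
  }
  if (clash) warning("read names shared across technical replicates; ",
                     "suffix-disambiguated")
  pair_set(ids, do.call(rbind, blocks), chrom,
           n_excluded = sum(vapply(ps_list, `[[`, 0L, "n_excluded")))
}
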
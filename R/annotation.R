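#' Construct an isoform model
#'
#' An isoform is an ordered chain of non-overlapping exons on one chromosome
#' and strand. Coordinates are 0-based half-open internally (BAM convention);
#' GTF input/output converts at the boundary.
#'
#' @param isoform_id Transcript identifier.
#' @param gene_id Identifier of the parent gene.
#' @param chrom Sequence (chromosome) name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of exon starts/ends (0-based half-open).
#'   Need not be sorted; they are sorted by start.
#' @return An object of class `IsoformModel`: a list with elements
#'   `isoform_id`, `gene_id`, `chrom`, `strand`, `starts`, `ends`,
#'   `length` (sum of exon widths, the transcript length l_k) and `cum`
#'   (cumulative transcript offset of each exon start, genomic-forward).
#' @export
isoform_model <- function(isoform_id, gene_id, chrom, strand, starts, ends) {
  stopifnot(length(starts) == length(ends), length(starts) >= 1L)
  if (length(isoform_id) != 1L || !nzchar(isoform_id))
    stop("isoform_id must be a single non-empty string")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for isoform ", isoform_id)
  o <- order(starts)
  starts <- as.integer(starts[o]); ends <- as.integer(ends[o])
  if (any(starts >= ends))
    stop("isoform ", isoform_id, ": exon start must be < end")
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)]))
    stop("isoform ", isoform_id, ": exons overlap")
  w <- ends - starts
  structure(list(
    isoform_id = isoform_id, gene_id = gene_id, chrom = chrom,
    strand = strand, starts = starts, ends = ends,
    length = sum(w), cum = cumsum(c(0L, w[-length(w)]))
  ), class = "IsoformModel")
}

#' Construct a gene model from isoform models
#'
#' @param gene_id Gene identifier.
#' @param isoforms List of [isoform_model()] objects. All must share one
#'   chromosome and strand (a "gene" split across chromosomes or strands has
#'   no usage composition and is rejected).
#' @return An object of class `GeneModel`: list with `gene_id`, `chrom`,
#'   `strand`, `isoforms` (named by isoform id), `K`, `span` (c(start, end),
#'   0-based half-open cover of all exons).
#' @export
gene_model <- function(gene_id, isoforms) {
  stopifnot(length(isoforms) >= 1L)
  ids <- vapply(isoforms, `[[`, "", "isoform_id")
  if (anyDuplicated(ids))
    stop("gene ", gene_id, ": duplicated isoform ids")
  chroms <- unique(vapply(isoforms, `[[`, "", "chrom"))
  strands <- unique(vapply(isoforms, `[[`, "", "strand"))
  if (length(chroms) != 1L || length(strands) != 1L)
    stop("gene ", gene_id, " spans multiple chromosomes or strands; ",
         "such genes are not supported")
  names(isoforms) <- ids
  structure(list(
    gene_id = gene_id, chrom = chroms, strand = strands,
    isoforms = isoforms, K = length(isoforms),
    span = c(min(vapply(isoforms, function(i) i$starts[1L], 1L)),
             max(vapply(isoforms, function(i) max(i$ends), 1L)))
  ), class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel", x$gene_id, sprintf("(%s%s)", x$chrom, x$strand),
      "with", x$K, "isoform(s):\n")
  for (iso in x$isoforms)
    cat("  ", iso$isoform_id, ": ", length(iso$starts), " exon(s), l_k = ",
        iso$length, " nt\n", sep = "")
  invisible(x)
}

#' Parse a GTF/GFF annotation into gene models
#'
#' Reads exon features with [rtracklayer::import()], groups exons into
#' isoforms and isoforms into genes. GTF 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param path Path to a GTF/GFF file.
#' @param gene_id_attr,transcript_id_attr Names of the attribute columns
#'   carrying the gene and transcript identifiers (Ensembl/UCSC default
#'   `"gene_id"` / `"transcript_id"`).
#' @return Named list of [gene_model()] objects.
#' @details Records of type other than `exon` are ignored, except that a
#'   `transcript` record whose id never appears on any exon is an error
#'   (an isoform without exons has no length). Exon records missing either
#'   identifier are skipped with a warning.
#' @export
parse_annotation <- function(path, gene_id_attr = "gene_id",
                             transcript_id_attr = "transcript_id") {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if (!all(c(gene_id_attr, transcript_id_attr) %in% names(mc)))
    stop("annotation lacks attribute(s) ", gene_id_attr, " / ",
         transcript_id_attr)
  type <- if ("type" %in% names(mc)) as.character(mc$type) else
    rep("exon", length(gr))
  gid <- as.character(mc[[gene_id_attr]])
  tid <- as.character(mc[[transcript_id_attr]])

  is_exon <- type == "exon"
  bad <- is_exon & (is.na(gid) | is.na(tid) | !nzchar(gid) | !nzchar(tid))
  if (any(bad)) {
    warning(sum(bad), " exon record(s) missing gene/transcript id skipped")
    is_exon <- is_exon & !bad
  }
  declared <- unique(tid[type == "transcript" & !is.na(tid)])
  with_exons <- unique(tid[is_exon])
  orphan <- setdiff(declared, with_exons)
  if (length(orphan))
    stop("isoform(s) without exons: ", paste(orphan, collapse = ", "))

  ex <- gr[is_exon]
  exg <- gid[is_exon]; ext <- tid[is_exon]
  genes <- list()
  for (g in unique(exg)) {
    sel <- exg == g
    isoforms <- lapply(unique(ext[sel]), function(t) {
      i <- sel & ext == t
      isoform_model(t, g,
                    chrom = as.character(GenomicRanges::seqnames(ex[i]))[1L],
                    strand = as.character(GenomicRanges::strand(ex[i]))[1L],
                    starts = GenomicRanges::start(ex[i]) - 1L,
                    ends = GenomicRanges::end(ex[i]))
    })
    genes[[g]] <- gene_model(g, isoforms)
  }
  genes
}

#' Serialize gene models back to GTF
#'
#' Inverse of [parse_annotation()] (exon records only); round-tripping a
#' parsed annotation reproduces identical models.
#'
#' @param genes Named list of `GeneModel` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) for (iso in g$isoforms) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     g$gene_id, iso$isoform_id)
    lines <- c(lines, sprintf("%s\tisoUsage\texon\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, iso$starts + 1L, iso$ends,
                              g$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Map a genomic position to a transcript offset
#'
#' Offsets run 5' to 3' along the transcript: for a minus-strand isoform
#' offset 0 is the rightmost exonic base. Positions falling in introns or
#' outside the isoform return `NA` ("off-isoform").
#'
#' @param iso An `IsoformModel`.
#' @param pos Integer vector of genomic positions (0-based).
#' @return Integer vector of transcript offsets in `[0, l_k)`, `NA` where
#'   off-isoform.
#' @export
genomic_to_transcript <- function(iso, pos) {
  fwd <- .fwd_offset(iso, pos)
  if (iso$strand == "-") ifelse(is.na(fwd), NA_integer_,
                                iso$length - 1L - fwd) else fwd
}

# Genomic-forward transcript offset (distance along the spliced transcript
# from its leftmost genomic base), ignoring strand. Fragment-length
# computations are strand-symmetric and use this form.
.fwd_offset <- function(iso, pos) {
  pos <- as.integer(pos)
  idx <- findInterval(pos, iso$starts)
  ok <- idx >= 1L & pos < iso$ends[pmax(idx, 1L)]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- iso$cum[idx[ok]] + (pos[ok] - iso$starts[idx[ok]])
  out
}

#' Map a transcript offset to its genomic position
#'
#' Inverse of [genomic_to_transcript()] on the exonic positions.
#'
#' @param iso An `IsoformModel`.
#' @param offset Integer vector of transcript offsets in `[0, l_k)`.
#' @return Integer vector of genomic positions (0-based).
#' @export
transcript_to_genomic <- function(iso, offset) {
  offset <- as.integer(offset)
  if (any(offset < 0L | offset >= iso$length))
    stop("transcript offset out of range [0, l_k)")
  if (iso$strand == "-") offset <- iso$length - 1L - offset
  idx <- findInterval(offset, iso$cum)
  iso$starts[idx] + (offset - iso$cum[idx])
}

# Project a transcript-forward interval [a, b) (genomic-forward offsets) onto
# genomic exon blocks; returns matrix with columns start, end (0-based
# half-open), one row per block, sorted by start.
.transcript_to_blocks <- function(iso, a, b) {
  stopifnot(a >= 0L, b <= iso$length, a < b)
  w <- iso$ends - iso$starts
  lo <- iso$cum; hi <- iso$cum + w
  keep <- which(hi > a & lo < b)
  bs <- iso$starts[keep] + pmax(0L, a - lo[keep])
  be <- iso$starts[keep] + (pmin(w[keep], b - lo[keep]))
  # merge genomically adjacent exons (zero-length intron)
  if (length(bs) > 1L) {
    join <- bs[-1L] == be[-length(be)]
    grp <- cumsum(c(TRUE, !join))
    bs <- tapply(bs, grp, min); be <- tapply(be, grp, max)
  }
  cbind(start = as.integer(bs), end = as.integer(be))
}
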
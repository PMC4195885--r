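#' Build a run manifest for a two-group analysis
#'
#' @param annotation Path to a GTF/GFF annotation.
#' @param group0,group1 Character vectors of BAM paths (>= 2 per group), or
#'   lists of character vectors to pool technical replicates into one
#'   biological replicate each (see [merge_technical_replicates()]).
#' @param config Named list of options overriding the defaults: `method`
#'   (`"SKK"`), `eps` (1e-4), `adjust` (`"BH"`), `alpha` (0.05), `permute`
#'   (`FALSE`), `B` (10000), `seed` (1), `min_reads` (10), `min_mapq` (0),
#'   `min_fragments` (1000), `fallback_mean` (250), `fallback_sd` (25).
#' @return Object of class `run_manifest`.
#' @export
run_manifest <- function(annotation, group0, group1, config = list()) {
  as_reps <- function(g) if (is.list(g)) lapply(g, as.character) else
    as.list(as.character(g))
  group0 <- as_reps(group0); group1 <- as_reps(group1)
  if (length(group0) < 2L || length(group1) < 2L)
    stop("at least two biological replicates per group required")
  paths <- c(annotation, unlist(group0), unlist(group1))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  defaults <- list(method = "SKK", eps = 1e-4, adjust = "BH", alpha = 0.05,
                   permute = FALSE, B = 10000L, seed = 1L, min_reads = 10L,
                   min_mapq = 0L, min_fragments = 1000L,
                   fallback_mean = 250, fallback_sd = 25)
  config <- utils::modifyList(defaults, config)
  structure(list(annotation = annotation, group0 = group0, group1 = group1,
                 config = config,
                 version = as.character(utils::packageVersion("isoUsage"))),
            class = "run_manifest")
}

#' Pool technical replicates into one biological replicate
#'
#' Loads read pairs for a gene from each technical-replicate BAM and pools
#' them into a single [pair_set()]; estimation then treats the pool as one
#' dataset. Identical to estimating from a concatenated BAM.
#'
#' @param bams Character vector of BAM paths (technical replicates of one
#'   biological replicate).
#' @param gene A `GeneModel`.
#' @param ... Filters passed to [load_read_pairs()].
#' @return A pooled `pair_set`.
#' @export
merge_technical_replicates <- function(bams, gene, ...) {
  merge_read_pairs(lapply(bams, load_read_pairs, gene = gene, ...))
}

.check_chroms <- function(bams, genes) {
  ann <- unique(vapply(genes, `[[`, "", "chrom"))
  for (b in bams) {
    sq <- names(Rsamtools::scanBamHeader(b)[[1L]]$targets)
    miss <- setdiff(ann, sq)
    if (length(miss) == length(ann))
      stop("chromosome name mismatch between annotation and ", b,
           "; annotation chromosomes not in BAM: ",
           paste(miss, collapse = ", "))
  }
}

#' Run the full two-step differential isoform usage analysis
#'
#' For every multi-isoform gene in the annotation: estimate usage in each
#' sample (fragment-length distribution estimated once per sample across
#' all genes), test the two groups, and adjust p-values across testable
#' genes. Deterministic given the manifest seed.
#'
#' @param manifest A [run_manifest()].
#' @param out_dir Optional directory; when given, `results.tsv` (per-gene
#'   tests), `usage.tsv` (per-sample estimates) and `manifest.json`-style
#'   run metadata (`run_info.txt`) are written there.
#' @return List with `results` (data.frame: gene_id, K, K_tested, method,
#'   statistic, p_value, p_adjusted, group0_usage, group1_usage, flags),
#'   `usage` (data.frame of per-sample theta-hat), `fld` (per-sample
#'   distributions), and `summary` counters
#'   (tested / untestable / single_isoform / insufficient).
#' @export
run_analysis <- function(manifest, out_dir = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest$config
  genes <- parse_annotation(manifest$annotation)
  reps <- c(manifest$group0, manifest$group1)
  grp <- rep(0:1, c(length(manifest$group0), length(manifest$group1)))
  sample_ids <- paste0("g", grp, "_s",
                       c(seq_along(manifest$group0),
                         seq_along(manifest$group1)))
  .check_chroms(unlist(reps), genes)

  # per-sample: pooled pair sets per gene, FLD, usage estimates
  usage_rows <- list(); flds <- list()
  estimates <- rep(list(list()), length(genes)); names(estimates) <- names(genes)
  for (s in seq_along(reps)) {
    pair_sets <- lapply(genes, function(g)
      merge_technical_replicates(reps[[s]], g, min_mapq = cfg$min_mapq))
    compats <- Map(build_compatibility, pair_sets, genes)
    fld <- withCallingHandlers(
      estimate_fld(unname(compats), genes,
                   min_fragments = cfg$min_fragments,
                   fallback_mean = cfg$fallback_mean,
                   fallback_sd = cfg$fallback_sd),
      warning = function(w) {
        message("[", sample_ids[s], "] ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    flds[[sample_ids[s]]] <- fld
    for (gname in names(genes)) {
      e <- estimate_gene_sample_usage(pair_sets[[gname]], genes[[gname]],
                                      fld, sample_id = sample_ids[s],
                                      min_reads = cfg$min_reads,
                                      start_seed = cfg$seed)
      estimates[[gname]][[sample_ids[s]]] <- e
      usage_rows[[length(usage_rows) + 1L]] <- data.frame(
        gene_id = e$gene_id, sample_id = sample_ids[s], group = grp[s],
        isoform_id = names(e$theta_hat),
        theta_hat = unname(e$theta_hat), p_hat = unname(e$p_hat),
        n_reads = e$n_reads, converged = e$converged,
        flags = paste(e$flags, collapse = ","))
    }
  }

  fmt_usage <- function(x) paste(sprintf("%s=%.4g", names(x), x),
                                 collapse = ";")
  res_rows <- list()
  counters <- c(tested = 0L, untestable = 0L, single_isoform = 0L,
                insufficient = 0L)
  for (gname in names(genes)) {
    g <- genes[[gname]]
    ests <- estimates[[gname]]
    if (g$K < 2L) {
      counters["single_isoform"] <- counters["single_isoform"] + 1L
      res_rows[[gname]] <- data.frame(
        gene_id = gname, K = g$K, K_tested = NA_integer_,
        method = NA_character_, statistic = NA_real_, p_value = NA_real_,
        group0_usage = NA_character_, group1_usage = NA_character_,
        flags = "single_isoform")
      next
    }
    ok <- vapply(ests, function(e) all(is.finite(e$theta_hat)), TRUE)
    e0 <- ests[grp == 0L & ok]; e1 <- ests[grp == 1L & ok]
    if (length(e0) < 2L || length(e1) < 2L) {
      counters["insufficient"] <- counters["insufficient"] + 1L
      res_rows[[gname]] <- data.frame(
        gene_id = gname, K = g$K, K_tested = NA_integer_,
        method = NA_character_, statistic = NA_real_, p_value = NA_real_,
        group0_usage = NA_character_, group1_usage = NA_character_,
        flags = "insufficient_usable_samples")
      next
    }
    res <- test_gene(e0, e1, method = cfg$method, eps = cfg$eps,
                     permute = cfg$permute, B = cfg$B, seed = cfg$seed,
                     gene_id = gname)
    if (is.na(res$p_value)) counters["untestable"] <-
        counters["untestable"] + 1L
    else counters["tested"] <- counters["tested"] + 1L
    res_rows[[gname]] <- data.frame(
      gene_id = gname, K = g$K,
      K_tested = if (is.null(res$group_means)) NA_integer_ else
        length(res$group_means$group0),
      method = res$method, statistic = res$statistic,
      p_value = res$p_value,
      group0_usage = if (is.null(res$group_means)) NA_character_ else
        fmt_usage(res$group_means$group0),
      group1_usage = if (is.null(res$group_means)) NA_character_ else
        fmt_usage(res$group_means$group1),
      flags = paste(res$flags, collapse = ","))
  }
  results <- do.call(rbind, res_rows)
  rownames(results) <- NULL
  results$p_adjusted <- adjust_pvalues(results$p_value,
                                       method = cfg$adjust)
  results <- results[, c("gene_id", "K", "K_tested", "method", "statistic",
                         "p_value", "p_adjusted", "group0_usage",
                         "group1_usage", "flags")]
  usage <- do.call(rbind, usage_rows)
  rownames(usage) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results, file.path(out_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(usage, file.path(out_dir, "usage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(paste("isoUsage version:", manifest$version),
                 paste("annotation:", manifest$annotation),
                 paste("group0:", paste(unlist(manifest$group0),
                                        collapse = " ")),
                 paste("group1:", paste(unlist(manifest$group1),
                                        collapse = " ")),
                 paste("config:", paste(names(cfg), unlist(cfg), sep = "=",
                                        collapse = " "))),
               file.path(out_dir, "run_info.txt"))
  }
  list(results = results, usage = usage, fld = flds, summary = counters)
}
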
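#' Run the full doublet-calling workflow
#'
#' Orchestrates: cleavage extraction (when paths are given) -> CPM
#' normalization -> replicate averaging of the TF tracks -> 3 bp / 2 bp
#' sliding-window smoothing -> genome-average baseline filter and local
#' maxima -> negative-binomial Wald enrichment over the control -> doublet
#' pairing and merging. Optionally assigns target genes and tests catalog
#' overlap. When `out_dir` is given, intermediate tables, the site BED and a
#' JSON run manifest (parameters plus the peak-count funnel) are written.
#'
#' @param tf,control lists of [cleavage_profile()] objects, or character
#'   vectors of BAM/SAM paths.
#' @param genome a [genome_index()]; required when paths are given.
#' @param mapq_min MAPQ cutoff for path inputs (default 10).
#' @param w,s smoothing window and step (defaults 3 and 2).
#' @param baseline_mult genome-average multiplier (default 3).
#' @param config an [nb_config()] (log2FC > 1.7, adjusted p < 1e-4 defaults).
#' @param d_min,d_max doublet spacing bounds (defaults 15 and 50).
#' @param genes optional [read_gene_annotation()] data.frame for target
#'   assignment.
#' @param upstream upstream window for target assignment (default 700).
#' @param catalog optional [read_target_catalog()] list for overlap
#'   enrichment.
#' @param out_dir optional output directory.
#' @return list of class `doublechec_run`: `maxima`, `enrichment`, `peaks`
#'   (retained), `sites`, `distance_histogram`, `targets`, `enrichment_table`,
#'   `funnel` (named counts: windows, maxima, enriched, sites), `params`.
#' @export
run_pipeline <- function(tf, control, genome = NULL, mapq_min = 10,
                         w = 3L, s = 2L, baseline_mult = 3,
                         config = nb_config(), d_min = 15L, d_max = 50L,
                         genes = NULL, upstream = 700L, catalog = NULL,
                         out_dir = NULL) {
  load_side <- function(x, label) {
    if (is.character(x)) {
      if (is.null(genome)) stop("genome_index required for path inputs")
      lapply(seq_along(x), function(i)
        extract_cleavage(x[i], genome, mapq_min = mapq_min, label = label,
                         replicate = i))
    } else if (inherits(x, "cleavage_profile")) list(x) else x
  }
  tf <- load_side(tf, "tf")
  control <- load_side(control, "control")
  if (length(tf) < 1L) stop("no TF sample")
  if (length(control) < 1L) stop("no control sample")
  if (is.null(genome)) genome <- tf[[1L]]$genome

  mean_tf <- mean_track(lapply(tf, cpm_normalize))
  smoothed <- smooth_track(mean_tf, c(tf, control), w = w, s = s)
  threshold <- genome_baseline(mean_tf, multiplier = baseline_mult)
  maxima <- find_local_maxima(smoothed, threshold)
  n_windows <- sum(vapply(smoothed$contigs, function(sc)
    if (is.null(sc)) 0L else length(sc$centers), 0L))

  condition <- c(rep("tf", length(tf)), rep("control", length(control)))
  if (nrow(maxima) == 0L) {
    enrichment <- NULL
    peaks <- maxima[0L, c("contig", "center")]
    peaks$padj <- numeric(0)
  } else {
    counts <- as.matrix(maxima[, attr(maxima, "samples"), drop = FALSE])
    rownames(counts) <- sprintf("%s:%d", maxima$contig, maxima$center)
    enrichment <- nb_wald_test(counts, condition, config = config)
    enrichment <- cbind(maxima[, c("contig", "center", "window_start",
                                   "window_end", "mean_cpm")], enrichment)
    peaks <- enrichment[enrichment$retained,
                        c("contig", "center", "padj"), drop = FALSE]
  }
  hist <- adjacent_distances(peaks)
  sites <- call_doublets(peaks, d_min = d_min, d_max = d_max)
  funnel <- c(windows = n_windows, maxima = nrow(maxima),
              enriched = nrow(peaks), sites = nrow(sites))

  targets <- NULL; enrichment_table <- NULL
  if (!is.null(genes)) {
    targets <- assign_targets(sites, genes, upstream = upstream)
    if (!is.null(catalog)) {
      enrichment_table <- fisher_overlap(targets$targets, catalog,
                                         universe = genes$gene_id)
    }
  }

  res <- structure(list(
    maxima = maxima, enrichment = enrichment, peaks = peaks, sites = sites,
    distance_histogram = hist, targets = targets,
    enrichment_table = enrichment_table, funnel = funnel, genome = genome,
    params = list(mapq_min = mapq_min, w = w, s = s,
                  baseline_mult = baseline_mult, threshold = threshold,
                  lfc_min = config$lfc_min, alpha = config$alpha,
                  d_min = d_min, d_max = d_max, upstream = upstream)),
    class = "doublechec_run")

  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.doublechec_run <- function(x, ...) {
  cat("doublechec run\n")
  cat(sprintf("  windows:  %d\n  maxima:   %d\n  enriched: %d\n  sites:    %d\n",
              x$funnel[["windows"]], x$funnel[["maxima"]],
              x$funnel[["enriched"]], x$funnel[["sites"]]))
  invisible(x)
}

# write tables, site BED and the JSON manifest for a pipeline run
write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$maxima, file.path(out_dir, "maxima.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$enrichment)) {
    utils::write.table(res$enrichment, file.path(out_dir, "enriched.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (nrow(res$sites)) {
    bed <- data.frame(contig = res$sites$contig, start = res$sites$start,
                      end = res$sites$end,
                      name = sprintf("doublet_%d", seq_len(nrow(res$sites))),
                      score = round(pmin(-log10(pmax(res$sites$score,
                                                     1e-300)), 1000), 3),
                      strand = ".")
    write_bed(bed, file.path(out_dir, "sites.bed"), res$genome)
  } else {
    writeLines(character(0), file.path(out_dir, "sites.bed"))
  }
  if (!is.null(res$targets)) {
    utils::write.table(res$targets$assignments,
                       file.path(out_dir, "targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$enrichment_table)) {
    utils::write.table(res$enrichment_table,
                       file.path(out_dir, "target_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(package = "doublechec",
                   version = as.character(utils::packageVersion("doublechec")),
                   params = res$params, funnel = as.list(res$funnel))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
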
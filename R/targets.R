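#' Assign high-confidence sites to downstream genes
#'
#' A gene is a target iff at least one site falls in its strand-aware upstream
#' window: `[anchor - upstream, anchor)` for `+` strand genes and
#' `(anchor, anchor + upstream]` for `-` strand genes, clipped at contig ends.
#' By default a site hits the window when its midpoint lies inside
#' (`mode = "midpoint"`); `mode = "interval"` counts any overlap of the merged
#' site interval with the window.
#'
#' @param sites data.frame from [call_doublets()] (needs `contig`, `midpoint`,
#'   and for interval mode `start`, `end`).
#' @param genes data.frame from [read_gene_annotation()].
#' @param upstream window length in bp (default 700).
#' @param mode `"midpoint"` (default) or `"interval"`.
#' @return list of class `target_assignment`: `targets` (character vector of
#'   target gene ids) and `assignments` (data.frame `gene_id`, `contig`,
#'   `site_midpoint`).
#' @export
assign_targets <- function(sites, genes, upstream = 700L,
                           mode = c("midpoint", "interval")) {
  mode <- match.arg(mode)
  upstream <- as.integer(upstream)
  win_start <- ifelse(genes$strand == "+", genes$position - upstream,
                      genes$position + 1L)
  win_end <- ifelse(genes$strand == "+", genes$position,
                    genes$position + upstream + 1L)  # half-open [start, end)
  win_start <- pmax(win_start, 0L)
  hits <- if (nrow(sites) == 0L || nrow(genes) == 0L) {
    integer(0)
  } else if (mode == "midpoint") {
    q <- GenomicRanges::GRanges(
      sites$contig,
      IRanges::IRanges(start = sites$midpoint + 1L, width = 1L))
    s <- GenomicRanges::GRanges(
      genes$contig, IRanges::IRanges(start = win_start + 1L, end = win_end))
    GenomicRanges::findOverlaps(q, s)
  } else {
    q <- GenomicRanges::GRanges(
      sites$contig,
      IRanges::IRanges(start = sites$start + 1L, end = sites$end))
    s <- GenomicRanges::GRanges(
      genes$contig, IRanges::IRanges(start = win_start + 1L, end = win_end))
    GenomicRanges::findOverlaps(q, s)
  }
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    assignments <- data.frame(gene_id = genes$gene_id[sh],
                              contig = genes$contig[sh],
                              site_midpoint = sites$midpoint[qh])
    assignments <- assignments[order(assignments$gene_id,
                                     assignments$site_midpoint), ,
                               drop = FALSE]
    rownames(assignments) <- NULL
  } else {
    assignments <- data.frame(gene_id = character(0), contig = character(0),
                              site_midpoint = integer(0))
  }
  structure(list(targets = sort(unique(assignments$gene_id)),
                 assignments = assignments, upstream = upstream, mode = mode),
            class = "target_assignment")
}

#' Fisher-exact overlap enrichment against a TF target catalog
#'
#' For each catalog entry, the overlap between the query gene set and the
#' catalog target set (both intersected with the gene universe) is tested with
#' a one-sided (enrichment) Fisher exact test — the hypergeometric upper tail
#' of the 2x2 table — and Bonferroni-corrected across the number of catalog
#' entries tested.
#'
#' @param query character vector of query gene ids (must lie in `universe`).
#' @param catalog named list, TF name -> character vector of target gene ids
#'   (see [read_target_catalog()]).
#' @param universe character vector of all annotated gene ids.
#' @return data.frame per TF: `tf`, `overlap` (k), `query_size` (a),
#'   `set_size` (b), `universe_size` (N), `pvalue`, `padj_bonferroni`, sorted
#'   by p-value.
#' @export
fisher_overlap <- function(query, catalog, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe)) {
    stop("query gene(s) outside the universe: ",
         setdiff(query, universe)[1L])
  }
  n_tf <- length(catalog)
  res <- lapply(names(catalog), function(tf) {
    b_set <- intersect(catalog[[tf]], universe)
    k <- length(intersect(query, b_set))
    a <- length(query); b <- length(b_set); N <- length(universe)
    p <- stats::phyper(k - 1L, b, N - b, a, lower.tail = FALSE)
    data.frame(tf = tf, overlap = k, query_size = a, set_size = b,
               universe_size = N, pvalue = p,
               padj_bonferroni = min(1, p * n_tf))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$pvalue, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}
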
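#' Write intervals as BED6
#'
#' Intervals are 0-based half-open internally, which is already the BED
#' convention. Output is sorted by genome contig order then start; out-of-bounds
#' intervals are an error.
#'
#' @param sites data.frame with columns `contig`, `start`, `end`, and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @param genome a [genome_index()] fixing contig order and bounds.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path, genome) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (!all(sites$contig %in% genome$contigs)) {
    stop("interval on contig absent from genome_index: ",
         setdiff(sites$contig, genome$contigs)[1L])
  }
  lens <- genome$lengths[sites$contig]
  if (any(sites$start < 0) || any(sites$end > lens) ||
      any(sites$start >= sites$end)) {
    stop("interval out of bounds (need 0 <= start < end <= contig length)")
  }
  name <- if (is.null(sites$name)) {
    sprintf("site_%d", seq_len(nrow(sites)))
  } else as.character(sites$name)
  score <- if (is.null(sites$score)) rep(0, nrow(sites)) else sites$score
  strand <- if (is.null(sites$strand)) rep(".", nrow(sites)) else
    as.character(sites$strand)
  ord <- order(match(sites$contig, genome$contigs), sites$start, sites$end)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   sites$contig[ord], as.integer(sites$start[ord]),
                   as.integer(sites$end[ord]), name[ord],
                   format(score[ord], trim = TRUE), strand[ord])
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file (3-6 columns)
#'
#' @param path BED path.
#' @return data.frame with `contig`, `start`, `end` and, when present,
#'   `name`, `score`, `strand` (0-based half-open, as on disk).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(vapply(fields, length, 1L))
  if (ncol < 3L) stop("BED needs >= 3 columns: ", path)
  out <- data.frame(
    contig = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)))
  if (ncol >= 4L) out$name <- vapply(fields, `[[`, "", 4L)
  if (ncol >= 5L) out$score <- suppressWarnings(
    as.numeric(vapply(fields, `[[`, "", 5L)))
  if (ncol >= 6L) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Write a per-base track as bedGraph
#'
#' Runs of equal value are collapsed; zero runs are omitted, so an all-zero
#' track yields an empty file. Values must be finite.
#'
#' @param values named list of per-contig numeric vectors (one value per base),
#'   or a track object with a `values`/`counts` element.
#' @param path output path.
#' @param genome a [genome_index()].
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, path, genome) {
  values <- as_track_values(values)
  check_track_layout(values, genome, "bedGraph")
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in genome$contigs) {
    v <- values[[ctg]]
    if (any(!is.finite(v))) stop("non-finite value on contig ", ctg)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ctg, starts[keep], ends[keep],
                       format(r$values[keep], trim = TRUE, digits = 10)),
               con)
  }
  invisible(path)
}

#' Read a bedGraph back into a per-base track
#'
#' @param path bedGraph path.
#' @param genome a [genome_index()]; uncovered bases are 0.
#' @return named list of per-contig numeric vectors.
#' @export
read_bedgraph <- function(path, genome) {
  values <- lapply(genome$lengths, function(n) numeric(n))
  names(values) <- genome$contigs
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ctg <- vapply(fields, `[[`, "", 1L)
    if (!all(ctg %in% genome$contigs)) {
      stop("bedGraph contig absent from genome_index: ",
           setdiff(ctg, genome$contigs)[1L])
    }
    s <- as.integer(vapply(fields, `[[`, "", 2L))
    e <- as.integer(vapply(fields, `[[`, "", 3L))
    val <- as.numeric(vapply(fields, `[[`, "", 4L))
    for (i in seq_along(ctg)) {
      values[[ctg[i]]][(s[i] + 1L):e[i]] <- val[i]
    }
  }
  values
}

# Accept raw per-contig lists or package track objects interchangeably.
as_track_values <- function(x) {
  if (inherits(x, "cleavage_profile")) return(x$counts)
  if (inherits(x, c("cpm_track", "mean_cpm_track"))) return(x$values)
  stopifnot(is.list(x))
  x
}

#' Read gene anchors from GFF3/GTF or BED
#'
#' Produces one record per gene with the start-codon anchor used for
#' upstream-window target assignment: the leftmost coordinate for `+` strand
#' genes and the rightmost for `-` strand genes, 0-based. GFF/GTF coordinates
#' (1-based closed) are converted on read; BED is taken as 0-based half-open.
#'
#' @param path annotation path (`.gff`, `.gff3`, `.gtf`, or `.bed`).
#' @param genome a [genome_index()]; genes on unknown contigs are skipped with
#'   a warning.
#' @param feature for GFF/GTF, which feature type anchors the gene:
#'   `"gene"` (default) or `"CDS"` (true start-codon convention).
#' @return data.frame with columns `gene_id`, `contig`, `position` (0-based
#'   start-codon anchor), `strand`.
#' @export
read_gene_annotation <- function(path, genome,
                                 feature = c("gene", "CDS")) {
  feature <- match.arg(feature)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    bed <- read_bed(path)
    if (is.null(bed$strand)) stop("BED gene annotation needs a strand column")
    if (is.null(bed$name)) stop("BED gene annotation needs a name column")
    genes <- data.frame(
      gene_id = bed$name, contig = bed$contig,
      left = bed$start, right = bed$end - 1L, strand = bed$strand)
  } else {
    gr <- rtracklayer::import(path)
    gr <- gr[as.character(gr$type) == feature]
    if (length(gr) == 0L) stop("no '", feature, "' features in ", path)
    str <- as.character(BiocGenerics::strand(gr))
    if (any(str == "*")) stop("gene annotation is missing strand")
    ids <- if (!is.null(gr$ID)) as.character(gr$ID)
      else if (!is.null(gr$gene_id)) as.character(gr$gene_id)
      else if (!is.null(gr$Name)) as.character(gr$Name)
      else stop("cannot find a gene id attribute (ID/gene_id/Name)")
    if (feature == "CDS") {
      # several CDS rows per gene: anchor at the strand-aware extreme
      spl <- split(seq_along(gr), ids)
      left <- vapply(spl, function(i) min(BiocGenerics::start(gr)[i]), 1)
      right <- vapply(spl, function(i) max(BiocGenerics::end(gr)[i]), 1)
      ctg <- vapply(spl, function(i)
        as.character(GenomicRanges::seqnames(gr))[i[1L]], "")
      st <- vapply(spl, function(i) str[i[1L]], "")
      genes <- data.frame(gene_id = names(spl), contig = ctg,
                          left = left - 1L, right = right - 1L, strand = st)
    } else {
      genes <- data.frame(
        gene_id = ids,
        contig = as.character(GenomicRanges::seqnames(gr)),
        left = BiocGenerics::start(gr) - 1L,
        right = BiocGenerics::end(gr) - 1L,
        strand = str)
    }
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene annotation is missing strand")
  }
  known <- genes$contig %in% genome$contigs
  if (!all(known)) {
    warning(sum(!known), " gene(s) on contigs absent from genome_index ",
            "skipped")
    genes <- genes[known, , drop = FALSE]
  }
  pos <- ifelse(genes$strand == "+", genes$left, genes$right)
  out <- data.frame(gene_id = genes$gene_id, contig = genes$contig,
                    position = as.integer(pos), strand = genes$strand)
  ok <- out$position >= 0 & out$position < genome$lengths[out$contig]
  if (!all(ok)) {
    warning(sum(!ok), " gene anchor(s) outside contig bounds skipped")
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a TF target catalog (TSV: tf_name, gene_id)
#'
#' @param path two-column TSV; a header line naming the columns is optional.
#' @return named list mapping TF name to a character vector of unique target
#'   gene ids.
#' @export
read_target_catalog <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("tf_name", "gene_id"),
                          colClasses = "character", quote = "")
  if (nrow(df) && identical(tolower(df$tf_name[1L]), "tf_name")) {
    df <- df[-1L, , drop = FALSE]
  }
  if (any(!nzchar(df$gene_id))) stop("empty gene id in target catalog")
  lapply(split(df$gene_id, df$tf_name), unique)
}
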
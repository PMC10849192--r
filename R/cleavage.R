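#' Per-base cleavage-event profile
#'
#' One integer count per genomic base: the number of retained reads whose
#' cleavage-adjacent (5'-most sequenced) base maps there. `n` is the library
#' size (total retained reads), used for CPM normalization.
#'
#' @param counts named list of per-contig integer vectors matching `genome`.
#' @param genome a [genome_index()].
#' @param label sample label.
#' @param replicate replicate id.
#' @return object of class `cleavage_profile`.
#' @export
cleavage_profile <- function(counts, genome, label = "sample",
                             replicate = 1L) {
  check_track_layout(counts, genome, "cleavage profile")
  if (any(vapply(counts, function(x) any(x < 0 | x != round(x)), TRUE))) {
    stop("cleavage counts must be non-negative integers")
  }
  structure(list(counts = counts, n = sum(vapply(counts, sum, 0)),
                 genome = genome, label = label, replicate = replicate),
            class = "cleavage_profile")
}

#' @export
print.cleavage_profile <- function(x, ...) {
  cat(sprintf("cleavage_profile '%s' (rep %s): %s cleavage events\n",
              x$label, x$replicate, format(x$n, big.mark = ",")))
  invisible(x)
}

# reference-consumed width of a CIGAR string (M/D/N/=/X advance the reference)
cigar_ref_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    m <- regmatches(cigar[i], ops[i])[[1L]]
    op <- substring(m, nchar(m), nchar(m))
    len <- as.integer(substring(m, 1L, nchar(m) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, 1L)
}

#' Extract single-base cleavage events from a BAM/SAM file
#'
#' Each retained alignment contributes one event at its 5'-most sequenced base
#' in genome coordinates: the leftmost aligned base for `+` strand alignments
#' and the rightmost aligned base for `-` strand alignments. In the ChEC-seq2
#' library design Read 1 starts at the repaired MNase cut, so this base marks
#' the cleavage site. Unmapped, secondary and supplementary alignments are
#' dropped, as are reads below the MAPQ cutoff (default 10). For paired-end
#' input only read 1 is used. Soft-clipping is ignored: the aligned interval
#' defines the position.
#'
#' @param path BAM (or SAM, converted transparently) file with mapped reads.
#' @param genome a [genome_index()]; alignments to contigs absent from it are
#'   an error.
#' @param mapq_min minimum MAPQ to retain a read (default 10).
#' @param drop_duplicates drop alignments flagged as PCR/optical duplicates
#'   (default FALSE; duplicates are retained).
#' @param label,replicate passed to [cleavage_profile()].
#' @return a [cleavage_profile()].
#' @export
extract_cleavage <- function(path, genome, mapq_min = 10,
                             drop_duplicates = FALSE, label = NULL,
                             replicate = 1L) {
  if (is.null(label)) label <- basename(path)
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (drop_duplicates) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "strand", "pos", "cigar", "mapq", "flag"))
  aln <- Rsamtools::scanBam(path, param = param)[[1L]]
  keep <- !is.na(aln$pos)
  # MAPQ 255 means "unavailable"; retained unless below the cutoff anyway
  keep <- keep & !is.na(aln$mapq) & aln$mapq >= mapq_min
  # paired-end: read 1 only (flag 0x1 paired, 0x40 first in pair)
  paired <- bitwAnd(aln$flag, 1L) > 0L
  keep <- keep & (!paired | bitwAnd(aln$flag, 64L) > 0L)
  rname <- as.character(aln$rname)[keep]
  if (length(rname) && !all(rname %in% genome$contigs)) {
    stop("alignment contig absent from genome_index: ",
         setdiff(rname, genome$contigs)[1L])
  }
  if (!any(keep)) stop("empty library: no reads retained from ", label)
  pos0 <- aln$pos[keep] - 1L
  minus <- as.character(aln$strand)[keep] == "-"
  if (any(minus)) {
    pos0[minus] <- pos0[minus] + cigar_ref_width(aln$cigar[keep][minus]) - 1L
  }
  counts <- lapply(genome$contigs, function(ctg) {
    p <- pos0[rname == ctg]
    if (any(p < 0 | p >= genome$lengths[[ctg]])) {
      stop("alignment outside contig bounds on ", ctg)
    }
    tabulate(p + 1L, nbins = genome$lengths[[ctg]])
  })
  names(counts) <- genome$contigs
  cleavage_profile(counts, genome, label = label, replicate = replicate)
}

#' CPM-normalize a cleavage profile
#'
#' `value[i] = count[i] * 1e6 / N` with `N` the library size, so the track
#' sums to one million over the genome.
#'
#' @param profile a [cleavage_profile()].
#' @return object of class `cpm_track` (per-contig numeric vectors).
#' @export
cpm_normalize <- function(profile) {
  stopifnot(inherits(profile, "cleavage_profile"))
  if (profile$n <= 0) stop("cannot CPM-normalize an empty library")
  values <- lapply(profile$counts, function(x) x * 1e6 / profile$n)
  structure(list(values = values, genome = profile$genome,
                 label = profile$label),
            class = "cpm_track")
}

#' Average CPM tracks across replicates
#'
#' Elementwise arithmetic mean of one or more CPM tracks sharing a genome.
#'
#' @param tracks list of `cpm_track` objects (or a single track).
#' @return object of class `mean_cpm_track` with `n_replicates` recorded.
#' @export
mean_track <- function(tracks) {
  if (inherits(tracks, "cpm_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, TRUE, "cpm_track")))
  genome <- tracks[[1L]]$genome
  for (t in tracks) {
    if (!identical(t$genome$contigs, genome$contigs) ||
        !identical(unname(t$genome$lengths), unname(genome$lengths))) {
      stop("tracks do not share a genome_index")
    }
  }
  values <- lapply(genome$contigs, function(ctg) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[ctg]])) / length(tracks)
  })
  names(values) <- genome$contigs
  structure(list(values = values, genome = genome,
                 n_replicates = length(tracks),
                 label = tracks[[1L]]$label),
            class = "mean_cpm_track")
}
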
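#' Distances between adjacent retained peaks
#'
#' Center-to-center distances between consecutive retained peaks within each
#' contig (never across contigs), with a histogram binned at 2 bp. This is the
#' distribution from which the 15-50 bp doublet spacing band is read off: true
#' binding sites show a secondary mode at the footprint-plus-flanking spacing.
#'
#' @param peaks data.frame with `contig` and `center` columns (retained peaks).
#' @param bin histogram bin width in bp (default 2).
#' @return list of class `distance_histogram`: `distances` (integer vector),
#'   `breaks`, `counts`.
#' @export
adjacent_distances <- function(peaks, bin = 2L) {
  d <- unlist(lapply(split(peaks$center, peaks$contig), function(ctr) {
    ctr <- sort(unique(as.integer(ctr)))
    if (length(ctr) < 2L) integer(0) else diff(ctr)
  }), use.names = FALSE)
  if (length(d)) {
    breaks <- seq.int(0L, (max(d) %/% bin + 1L) * bin, by = bin)
    counts <- as.integer(table(cut(d, breaks = breaks, right = FALSE)))
  } else {
    breaks <- integer(0); counts <- integer(0)
  }
  structure(list(distances = as.integer(d), breaks = breaks, counts = counts,
                 bin = as.integer(bin)),
            class = "distance_histogram")
}

#' Pair enriched peaks into doublets and merge them into sites
#'
#' Scanning each contig left to right, consecutive retained peak centers whose
#' distance lies in `[d_min, d_max]` (inclusive) form a doublet. Doublets that
#' share a peak are merged transitively into a single site spanning the
#' chain's extreme centers, so the output interval is
#' `[left center, right center + 1)` with the midpoint at
#' `floor((left + right) / 2)`. With `chain_merge = FALSE` every qualifying
#' consecutive pair becomes its own site instead.
#'
#' @param peaks data.frame with `contig`, `center`, and optionally `padj`
#'   columns (retained peaks only).
#' @param d_min,d_max inclusive spacing bounds in bp (defaults 15 and 50).
#' @param chain_merge merge chained doublets transitively (default TRUE).
#' @return data.frame of high-confidence sites: `contig`, `start`, `end`,
#'   `midpoint`, `n_peaks`, `members` (comma-separated member centers),
#'   `score` (minimum member `padj`, NA when unavailable).
#' @export
call_doublets <- function(peaks, d_min = 15L, d_max = 50L,
                          chain_merge = TRUE) {
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), midpoint = integer(0),
                      n_peaks = integer(0), members = character(0),
                      score = numeric(0))
  if (nrow(peaks) == 0L) return(empty)
  has_p <- !is.null(peaks$padj)
  out <- lapply(split(peaks, peaks$contig), function(pc) {
    ord <- order(pc$center)
    ctr <- as.integer(pc$center[ord])
    padj <- if (has_p) pc$padj[ord] else rep(NA_real_, length(ctr))
    if (length(ctr) < 2L) return(NULL)
    gap_ok <- diff(ctr) >= d_min & diff(ctr) <= d_max
    if (!any(gap_ok)) return(NULL)
    if (chain_merge) {
      # maximal runs of qualifying gaps become one merged site each
      r <- rle(gap_ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      first <- starts[runs]; last <- ends[runs] + 1L  # peak indices
    } else {
      first <- which(gap_ok); last <- first + 1L
    }
    data.frame(
      contig = pc$contig[1L],
      start = ctr[first],
      end = ctr[last] + 1L,
      midpoint = as.integer((ctr[first] + ctr[last]) %/% 2L),
      n_peaks = last - first + 1L,
      members = vapply(seq_along(first), function(i)
        paste(ctr[first[i]:last[i]], collapse = ","), ""),
      score = vapply(seq_along(first), function(i)
        suppressWarnings(min(padj[first[i]:last[i]])), 0))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Expand sites to fixed-width windows around their midpoints
#'
#' Each site becomes `midpoint - flank .. midpoint + flank` (width
#' `2*flank + 1`, e.g. 21 bp at the default flank of 10), clipped to contig
#' bounds; overlapping expanded intervals are merged.
#'
#' @param sites data.frame with `contig` and `midpoint` (e.g. from
#'   [call_doublets()]).
#' @param flank bp added on each side of the midpoint.
#' @param genome a [genome_index()] for clipping.
#' @return data.frame `contig`, `start`, `end` (0-based half-open, merged).
#' @export
expand_sites <- function(sites, flank, genome) {
  stopifnot(flank >= 0)
  if (nrow(sites) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0)))
  }
  start <- pmax(sites$midpoint - flank, 0L)
  end <- pmin(sites$midpoint + flank + 1L, genome$lengths[sites$contig])
  df <- data.frame(contig = sites$contig, start = as.integer(start),
                   end = as.integer(end))
  merged <- lapply(split(df, df$contig), function(dc) {
    dc <- dc[order(dc$start, dc$end), , drop = FALSE]
    s <- dc$start; e <- dc$end
    grp <- cumsum(c(1L, as.integer(s[-1L] > cummax(e[-length(e)]))))
    data.frame(contig = dc$contig[1L],
               start = as.integer(tapply(s, grp, min)),
               end = as.integer(tapply(e, grp, max)))
  })
  out <- do.call(rbind, merged)
  out <- out[order(match(out$contig, genome$contigs), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract site sequences from a genome FASTA
#'
#' One record per interval, id `contig:start-end` (0-based half-open),
#' uppercase plus-strand sequence — the format handed to external motif
#' discovery tools.
#'
#' @param intervals data.frame with `contig`, `start`, `end`.
#' @param fasta path to the genome FASTA, or a `Biostrings::DNAStringSet`.
#' @param out optional path; when given, sequences are written as FASTA.
#' @return a `Biostrings::DNAStringSet` (invisibly when `out` is given).
#' @export
extract_site_sequences <- function(intervals, fasta, out = NULL) {
  genome_seq <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(genome_seq) <- sub("\\s.*$", "", names(genome_seq))
  if (nrow(intervals)) {
    if (!all(intervals$contig %in% names(genome_seq))) {
      stop("interval on contig missing from FASTA: ",
           setdiff(intervals$contig, names(genome_seq))[1L])
    }
    lens <- Biostrings::width(genome_seq)[match(intervals$contig,
                                                names(genome_seq))]
    if (any(intervals$start < 0) || any(intervals$end > lens)) {
      stop("interval outside contig in FASTA")
    }
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(intervals)),
      function(i) {
        toupper(as.character(Biostrings::subseq(
          genome_seq[[intervals$contig[i]]],
          start = intervals$start[i] + 1L, end = intervals$end[i])))
      }, ""))
    names(seqs) <- sprintf("%s:%d-%d", intervals$contig, intervals$start,
                           intervals$end)
  } else {
    seqs <- Biostrings::DNAStringSet()
  }
  if (!is.null(out)) {
    Biostrings::writeXStringSet(seqs, out)
    return(invisible(seqs))
  }
  seqs
}
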
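#' Genome index: ordered contig names and lengths
#'
#' A minimal container fixing contig order and coordinate bounds for every
#' downstream track and interval. Contig order is the chrom.sizes file order
#' everywhere, so outputs are deterministic. All internal coordinates in this
#' package are 0-based, half-open.
#'
#' @param contigs character vector of unique contig names.
#' @param lengths integer-ish vector of positive contig lengths (bp).
#' @return An object of class `genome_index` with elements `contigs` and
#'   `lengths` (named by contig).
#' @export
genome_index <- function(contigs, lengths) {
  contigs <- as.character(contigs)
  lengths <- as.numeric(lengths)
  if (length(contigs) == 0L) stop("no contigs")
  if (length(contigs) != length(lengths)) {
    stop("contigs and lengths differ in length")
  }
  if (anyDuplicated(contigs)) {
    stop("duplicate contig name: ", contigs[duplicated(contigs)][1L])
  }
  if (any(!is.finite(lengths)) || any(lengths < 1) ||
      any(lengths != round(lengths))) {
    stop("non-positive length (contig lengths must be positive integers)")
  }
  names(lengths) <- contigs
  structure(list(contigs = contigs, lengths = lengths),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: %d contig(s), %s bp total\n",
              length(x$contigs), format(genome_length(x), big.mark = ",")))
  invisible(x)
}

#' Total genome length
#'
#' @param genome a [genome_index()].
#' @return numeric, sum of contig lengths (the `L` in the 3x genome-average
#'   baseline).
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "genome_index"))
  sum(genome$lengths)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: contig name, length. Contigs keep file order.
#'
#' @param path path to the chrom.sizes file.
#' @return a [genome_index()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no contigs in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed chrom.sizes line ", bad[1L], " in ", path,
         ": expected name<tab>length")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(len)) {
    stop("malformed chrom.sizes line ", which(is.na(len))[1L], " in ", path,
         ": length does not parse")
  }
  if (any(len < 1 | len != round(len))) {
    stop("non-positive length at chrom.sizes line ",
         which(len < 1 | len != round(len))[1L])
  }
  genome_index(nm, len)
}

# shared validator: a per-contig list matches the genome layout
check_track_layout <- function(values, genome, what = "track") {
  stopifnot(inherits(genome, "genome_index"))
  if (!identical(names(values), genome$contigs)) {
    stop(what, " contigs do not match genome_index (order matters)")
  }
  n <- vapply(values, length, 1L)
  if (!all(n == genome$lengths)) {
    stop(what, " vector lengths do not match contig lengths")
  }
  invisible(TRUE)
}
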
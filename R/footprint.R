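#' Scan a genome for an IUPAC motif on both strands
#'
#' Matches the degenerate pattern on the plus strand and its reverse
#' complement (reported at plus-strand coordinates with `strand = "-"`).
#' Overlapping matches are all reported.
#'
#' @param fasta genome FASTA path or a `Biostrings::DNAStringSet`.
#' @param pattern IUPAC string over `ACGTNRYSWKMBDHV`.
#' @return data.frame `contig`, `start`, `end` (0-based half-open), `strand`,
#'   with the pattern stored as an attribute.
#' @export
scan_iupac <- function(fasta, pattern) {
  pattern <- toupper(pattern)
  letters_ok <- strsplit("ACGTNRYSWKMBDHV", "")[[1L]]
  bad <- setdiff(strsplit(pattern, "")[[1L]], letters_ok)
  if (length(bad)) stop("invalid IUPAC letter in pattern: ", bad[1L])
  genome_seq <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(genome_seq) <- sub("\\s.*$", "", names(genome_seq))
  fwd <- Biostrings::DNAString(pattern)
  rev <- Biostrings::reverseComplement(fwd)
  hits <- lapply(names(genome_seq), function(ctg) {
    subj <- genome_seq[[ctg]]
    one <- function(pat, strand) {
      m <- Biostrings::matchPattern(pat, subj, fixed = "subject")
      if (length(m) == 0L) return(NULL)
      data.frame(contig = ctg, start = Biostrings::start(m) - 1L,
                 end = Biostrings::end(m), strand = strand)
    }
    plus <- one(fwd, "+")
    minus <- if (as.character(rev) == as.character(fwd)) NULL else
      one(rev, "-")
    rbind(plus, minus)
  })
  hits <- hits[!vapply(hits, is.null, TRUE)]
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0))
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pattern") <- pattern
  out
}

#' Strand-oriented average cleavage over a set of sites (footprint metaplot)
#'
#' For each site the track values over `[start - w, end + w)` are taken; minus
#' strand sites contribute the same genomic window reversed, so offsets are
#' anchored at the motif's 5' end on the motif strand (offset 0 = first motif
#' base). Values are averaged elementwise across sites. All sites must share
#' one body length; sites whose flanked window leaves the genome are dropped
#' with a warning.
#'
#' @param track a [mean_track()] result (or `cpm_track`).
#' @param sites data.frame `contig`, `start`, `end`, `strand` (strand optional,
#'   defaults to `+`; set `orient = FALSE` to ignore it).
#' @param w flank in bp on each side.
#' @param orient reverse minus-strand windows (default TRUE).
#' @return list of class `metaplot`: `offset` (from `-w`), `mean` (average
#'   signal per offset), `n_sites`, `body_length`.
#' @export
metaplot <- function(track, sites, w = 100L, orient = TRUE) {
  stopifnot(w >= 0)
  values <- as_track_values(track)
  genome <- track$genome
  if (nrow(sites) == 0L) stop("empty site set")
  body <- unique(sites$end - sites$start)
  if (length(body) != 1L) stop("sites must share one body length")
  strand <- if (is.null(sites$strand)) rep("+", nrow(sites)) else
    as.character(sites$strand)
  lens <- genome$lengths[sites$contig]
  ok <- sites$start - w >= 0 & sites$end + w <= lens &
    sites$contig %in% genome$contigs
  if (!all(ok)) {
    warning(sum(!ok), " site(s) out of bounds after flanking dropped")
    sites <- sites[ok, , drop = FALSE]
    strand <- strand[ok]
  }
  if (nrow(sites) == 0L) stop("empty site set (all sites out of bounds)")
  width <- body + 2L * w
  acc <- numeric(width)
  for (i in seq_len(nrow(sites))) {
    win <- values[[sites$contig[i]]][
      (sites$start[i] - w + 1L):(sites$end[i] + w)]
    if (orient && strand[i] == "-") win <- base::rev(win)
    acc <- acc + win
  }
  structure(list(offset = seq.int(-w, body + w - 1L),
                 mean = acc / nrow(sites),
                 n_sites = nrow(sites), body_length = body, w = w),
            class = "metaplot")
}

#' Width of the protected region in a footprint metaplot
#'
#' Reports the length of the maximal contiguous run of offsets within the site
#' body whose mean signal falls below 50% of the mean flanking signal, where
#' the flanks are the offsets beyond `flank_reference` bp outside the body.
#' This is a reporting convenience for reading the footprint width off a
#' metaplot; a flat metaplot returns 0.
#'
#' @param meta a [metaplot()].
#' @param flank_reference bp outside the body beyond which offsets count as
#'   background flank (must be < the metaplot's `w`).
#' @param fraction protection cutoff as a fraction of flank signal
#'   (default 0.5).
#' @return integer width in bp.
#' @export
protection_width <- function(meta, flank_reference, fraction = 0.5) {
  stopifnot(inherits(meta, "metaplot"), flank_reference >= 0,
            flank_reference < meta$w)
  off <- meta$offset
  flank <- off < -flank_reference | off >= meta$body_length + flank_reference
  flank_mean <- mean(meta$mean[flank])
  if (!is.finite(flank_mean) || flank_mean <= 0) return(0L)
  body <- off >= 0 & off < meta$body_length
  below <- meta$mean[body] < fraction * flank_mean
  if (!any(below)) return(0L)
  r <- rle(below)
  as.integer(max(r$lengths[r$values]))
}
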
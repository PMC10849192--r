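#' Smooth tracks with a sliding window
#'
#' Windows of width `w` (default 3 bp) every `s` bp (default 2 bp), starting at
#' the first full window: 0-based centers `c = (w-1)/2, (w-1)/2 + s, ...`.
#' For each center the window mean of the averaged CPM track and, per replicate
#' profile, the integer window SUM of raw counts are recorded. The sums feed
#' the negative-binomial test, which needs counts; partial edge windows are
#' dropped and contigs shorter than `w` are skipped with a warning.
#'
#' @param mean_track a [mean_track()] result (averaged CPM).
#' @param raw_profiles list of [cleavage_profile()] objects (TF replicates then
#'   control replicates) sharing the genome; may be empty.
#' @param w odd window width in bp.
#' @param s step size in bp.
#' @return object of class `smoothed_track`: per contig, `centers` (0-based),
#'   `mean_cpm`, and a `raw` integer matrix (centers x samples).
#' @export
smooth_track <- function(mean_track, raw_profiles = list(), w = 3L, s = 2L) {
  stopifnot(inherits(mean_track, "mean_cpm_track"))
  w <- as.integer(w); s <- as.integer(s)
  if (w %% 2L != 1L || w < 1L) stop("window width w must be odd and >= 1")
  if (s < 1L) stop("step s must be >= 1")
  genome <- mean_track$genome
  for (p in raw_profiles) check_track_layout(p$counts, genome, "raw profile")
  labels <- vapply(raw_profiles, function(p)
    paste0(p$label, "_rep", p$replicate), "")
  half <- (w - 1L) %/% 2L
  per_contig <- lapply(genome$contigs, function(ctg) {
    len <- genome$lengths[[ctg]]
    if (len < w) {
      warning("contig ", ctg, " shorter than window width; skipped")
      return(NULL)
    }
    centers <- seq.int(half, len - 1L - half, by = s)
    win_stat <- function(v) {
      cs <- cumsum(c(0, v))
      cs[centers + half + 2L] - cs[centers - half + 1L]
    }
    raw <- if (length(raw_profiles)) {
      m <- vapply(raw_profiles, function(p) win_stat(p$counts[[ctg]]),
                  numeric(length(centers)))
      matrix(as.integer(m), ncol = length(raw_profiles),
             dimnames = list(NULL, labels))
    } else {
      matrix(integer(0), nrow = length(centers), ncol = 0L)
    }
    list(centers = as.integer(centers),
         mean_cpm = win_stat(mean_track$values[[ctg]]) / w,
         raw = raw)
  })
  names(per_contig) <- genome$contigs
  structure(list(contigs = per_contig, genome = genome, w = w, s = s,
                 samples = labels),
            class = "smoothed_track")
}

#' Genome-average baseline threshold
#'
#' Three times (by default) the genome-wide mean per-base value of the averaged
#' CPM track. The genome mean is computed from the actual track sum rather than
#' assumed to be 1e6/L, so averaging replicates of unequal depth is handled
#' exactly.
#'
#' @param mean_track a [mean_track()] result.
#' @param multiplier baseline multiplier (default 3).
#' @return numeric threshold in CPM units.
#' @export
genome_baseline <- function(mean_track, multiplier = 3) {
  stopifnot(inherits(mean_track, "mean_cpm_track"))
  L <- genome_length(mean_track$genome)
  total <- sum(vapply(mean_track$values, sum, 0))
  multiplier * total / L
}

#' Baseline-filter smoothed windows and find local maxima
#'
#' A window is a local maximum iff its mean CPM is at or above `threshold` and
#' strictly greater than the window means at the immediately adjacent centers
#' (genomic neighbors at `c - s` and `c + s`, whether or not those neighbors
#' themselves passed the filter). Missing neighbors at contig ends count as
#' -Inf, so edge windows can be maxima. The default `plateau = "keep-left"`
#' keeps the left window of an exact tie: single-base cleavage tracks are
#' sparse, so a spike falling midway between two window centers produces two
#' windows with exactly equal means (both flanked by zeros) and a strict rule
#' would silently drop the peak; `plateau = "none"` applies strict inequality
#' on both sides instead.
#'
#' @param smoothed a [smooth_track()] result.
#' @param threshold baseline from [genome_baseline()].
#' @param plateau `"keep-left"` (default; left edge of an exact plateau kept)
#'   or `"none"` (strict inequality on both sides).
#' @return data.frame with one row per local maximum: `contig`, `center`,
#'   `window_start`, `window_end` (0-based half-open), `mean_cpm`, and one
#'   raw-count column per sample; `threshold` stored as an attribute.
#' @export
find_local_maxima <- function(smoothed, threshold,
                              plateau = c("keep-left", "none")) {
  stopifnot(inherits(smoothed, "smoothed_track"), threshold >= 0)
  plateau <- match.arg(plateau)
  half <- (smoothed$w - 1L) %/% 2L
  rows <- lapply(names(smoothed$contigs), function(ctg) {
    sc <- smoothed$contigs[[ctg]]
    if (is.null(sc)) return(NULL)
    m <- sc$mean_cpm
    left <- c(-Inf, m[-length(m)])
    right <- c(m[-1L], -Inf)
    is_max <- if (plateau == "keep-left") {
      m > left & m >= right
    } else {
      m > left & m > right
    }
    keep <- which(is_max & m >= threshold)
    if (!length(keep)) return(NULL)
    df <- data.frame(contig = ctg, center = sc$centers[keep],
                     window_start = sc$centers[keep] - half,
                     window_end = sc$centers[keep] + half + 1L,
                     mean_cpm = m[keep])
    cbind(df, as.data.frame(sc$raw[keep, , drop = FALSE]))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else {
    df <- data.frame(contig = character(0), center = integer(0),
                     window_start = integer(0), window_end = integer(0),
                     mean_cpm = numeric(0))
    for (nm in smoothed$samples) df[[nm]] <- integer(0)
    df
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "samples") <- smoothed$samples
  out
}
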
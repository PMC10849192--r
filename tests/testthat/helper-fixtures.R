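# shared fixture builders: tiny genomes, profiles and SAM files, all built in
# code at test time

tiny_genome <- function(lengths = c(chrI = 1000, chrII = 800)) {
  genome_index(names(lengths), unname(lengths))
}

# cleavage profile from a named list of (position -> count) maps, positions
# 0-based
profile_from_events <- function(genome, events, label = "tf",
                                replicate = 1L) {
  counts <- lapply(genome$contigs, function(ctg) {
    v <- integer(genome$lengths[[ctg]])
    ev <- events[[ctg]]
    if (!is.null(ev)) v[as.integer(names(ev)) + 1L] <- as.integer(ev)
    v
  })
  names(counts) <- genome$contigs
  cleavage_profile(counts, genome, label = label, replicate = replicate)
}

# minimal single-end SAM writer; reads = data.frame(qname, flag, contig,
# pos1, mapq, cigar)
write_test_sam <- function(genome, reads, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", genome$contigs, genome$lengths))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  reads$qname, reads$flag, reads$contig, reads$pos1,
                  reads$mapq, reads$cigar)
  writeLines(c(hdr, body), path)
  path
}

# per-base vector -> mean_cpm_track without CPM bookkeeping (direct values)
mean_track_from_values <- function(genome, values, n_replicates = 1L) {
  check_layout <- vapply(values, length, 1L)
  stopifnot(all(check_layout == genome$lengths))
  structure(list(values = values, genome = genome,
                 n_replicates = n_replicates, label = "test"),
            class = "mean_cpm_track")
}

# brute-force smoothing + maxima oracle: direct scan over all full windows;
# plateau rule matches the package default (keep-left)
oracle_maxima <- function(values, w = 3L, s = 2L, threshold = 0,
                          strict = FALSE) {
  half <- (w - 1L) %/% 2L
  n <- length(values)
  if (n < w) return(integer(0))
  centers <- seq.int(half, n - 1L - half, by = s)
  means <- vapply(centers, function(c0) {
    mean(values[(c0 - half + 1L):(c0 + half + 1L)])
  }, 0)
  keep <- integer(0)
  for (i in seq_along(centers)) {
    left <- if (i > 1L) means[i - 1L] else -Inf
    right <- if (i < length(centers)) means[i + 1L] else -Inf
    ok <- if (strict) means[i] > left && means[i] > right else
      means[i] > left && means[i] >= right
    if (means[i] >= threshold && ok) keep <- c(keep, centers[i])
  }
  keep
}

# brute-force doublet oracle: enumerate qualifying consecutive pairs, then
# merge transitively by shared peaks
oracle_doublets <- function(centers, d_min = 15L, d_max = 50L) {
  centers <- sort(unique(centers))
  if (length(centers) < 2L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  pairs <- list()
  for (i in seq_len(length(centers) - 1L)) {
    d <- centers[i + 1L] - centers[i]
    if (d >= d_min && d <= d_max) pairs[[length(pairs) + 1L]] <- c(i, i + 1L)
  }
  if (!length(pairs)) return(data.frame(start = integer(0), end = integer(0)))
  # transitive merge over shared peak indices
  groups <- list(pairs[[1L]])
  for (p in pairs[-1L]) {
    last <- groups[[length(groups)]]
    if (any(p %in% last)) {
      groups[[length(groups)]] <- union(last, p)
    } else {
      groups[[length(groups) + 1L]] <- p
    }
  }
  data.frame(
    start = vapply(groups, function(g) centers[min(g)], 1L),
    end = vapply(groups, function(g) centers[max(g)] + 1L, 1L))
}

# hypergeometric upper-tail sum oracle for the one-sided Fisher test
oracle_fisher <- function(k, a, b, N) {
  i <- k:min(a, b)
  sum(exp(lchoose(b, i) + lchoose(N - b, a - i) - lchoose(N, a)))
}
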
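#' Simulation configuration for planted-doublet cleavage tracks
#'
#' The generator emulates the structure the pipeline is built for: a shared
#' smooth accessibility landscape cut by both the TF-MNase and soluble-MNase
#' libraries, with the TF library additionally carrying a pair of single-base
#' cleavage spikes flanking each planted (protected) binding site. Defaults
#' follow the stated validation world: a 200 kb genome, 40 sites, 15-50 bp
#' doublet spacing, an 8-12 bp protected gap, about 60 expected TF reads per
#' spike over a 0.5 read/bp background, NB dispersion 0.1, and 3+3 replicates.
#'
#' @param genome_length total genome length in bp.
#' @param n_contigs number of equal-length contigs.
#' @param n_sites number of planted sites.
#' @param spacing doublet spacing d in bp: a single value or an inclusive
#'   range to draw uniformly per site (default `c(15, 50)`).
#' @param gap protected-gap width g in bp: single value or range
#'   (default `c(8, 12)`).
#' @param occupancy expected TF reads per flanking spike per replicate.
#' @param depth expected background reads per bp per replicate.
#' @param dispersion NB dispersion (`Var = mu + dispersion * mu^2`); 0 gives
#'   Poisson counts.
#' @param n_tf,n_control replicate counts.
#' @param roughness lognormal sigma of the accessibility landscape.
#' @param smooth_bp moving-average width used to smooth the accessibility
#'   field (correlation length of accessibility, default 200 bp).
#' @param protection_factor accessibility multiplier inside protected gaps
#'   (default 0.1).
#' @param jitter_spikes apply +/-1 bp uniform jitter to each spike read
#'   (default FALSE; mimics end-repair heterogeneity).
#' @param seed integer seed fixing all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L, n_contigs = 2L,
                       n_sites = 40L, spacing = c(15L, 50L), gap = c(8L, 12L),
                       occupancy = 60, depth = 0.5, dispersion = 0.1,
                       n_tf = 3L, n_control = 3L, roughness = 0.5,
                       smooth_bp = 200L, protection_factor = 0.1,
                       jitter_spikes = FALSE, seed = 1L) {
  spacing <- as.integer(range(spacing))
  gap <- as.integer(range(gap))
  stopifnot(genome_length > 0, n_contigs >= 1, n_sites >= 0,
            occupancy >= 0, depth >= 0, dispersion >= 0,
            n_tf >= 1, n_control >= 1, roughness >= 0,
            protection_factor >= 0)
  if (n_sites * (spacing[2L] + 2L) >= genome_length) {
    stop("too many sites for the genome length")
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_contigs = as.integer(n_contigs),
                 n_sites = as.integer(n_sites), spacing = spacing, gap = gap,
                 occupancy = occupancy, depth = depth,
                 dispersion = dispersion, n_tf = as.integer(n_tf),
                 n_control = as.integer(n_control), roughness = roughness,
                 smooth_bp = as.integer(smooth_bp),
                 protection_factor = protection_factor,
                 jitter_spikes = isTRUE(jitter_spikes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# NB draw parameterized by mean and dispersion; dispersion 0 -> Poisson
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# moving-average smoothed standard-normal field of length n (unit variance)
smooth_field <- function(n, width) {
  z <- stats::rnorm(n + width - 1L)
  cs <- cumsum(z)
  sm <- (cs[width:(n + width - 1L)] -
           c(0, cs[seq_len(n - 1L)])) / sqrt(width)
  sm
}

#' Simulate TF and control cleavage tracks with planted doublet sites
#'
#' Draws a shared lognormal accessibility landscape, plants non-overlapping
#' sites (left/right spike positions `d` bp apart with a protected gap of `g`
#' bp centered between them where accessibility drops to
#' `protection_factor`), then draws per-base NB counts: control replicates
#' see `depth * accessibility`; TF replicates see the same background plus an
#' NB spike of mean `occupancy` at each flanking position. All randomness
#' comes from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_result`: `tf` and `control` (lists of
#'   [cleavage_profile()]), `truth` (data.frame per site: `contig`, `left`,
#'   `right`, `spacing`, `gap`, `protected_start`, `protected_end`,
#'   `midpoint`, `occupancy`), `genome`, `config`.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  per <- config$genome_length %/% config$n_contigs
  lens <- rep(per, config$n_contigs)
  lens[config$n_contigs] <- config$genome_length -
    per * (config$n_contigs - 1L)
  genome <- genome_index(sprintf("sim_%d", seq_len(config$n_contigs)), lens)
  # shared accessibility landscape, lognormal with mean ~1
  acc <- lapply(lens, function(n) {
    exp(config$roughness * smooth_field(n, min(config$smooth_bp, n)) -
          config$roughness^2 / 2)
  })
  names(acc) <- genome$contigs
  # plant non-overlapping sites; the exclusion margin exceeds the doublet
  # spacing band's upper bound so two planted sites can never chain into one
  # called site
  margin <- config$spacing[2L] + 10L
  occupied <- lapply(lens, function(n) logical(n))
  truth <- vector("list", config$n_sites)
  tries <- 0L
  i <- 1L
  while (i <= config$n_sites) {
    tries <- tries + 1L
    if (tries > 200L * max(config$n_sites, 1L)) {
      stop("could not place all sites; reduce n_sites")
    }
    ctg <- sample.int(config$n_contigs, 1L, prob = lens)
    d <- if (config$spacing[1L] == config$spacing[2L]) config$spacing[1L]
      else sample(config$spacing[1L]:config$spacing[2L], 1L)
    g <- if (config$gap[1L] == config$gap[2L]) config$gap[1L]
      else sample(config$gap[1L]:config$gap[2L], 1L)
    lo <- 2L * config$smooth_bp  # keep clear of contig ends for metaplots
    hi <- lens[ctg] - 2L * config$smooth_bp - d
    if (hi <= lo) stop("contigs too short for site placement")
    left <- sample(lo:hi, 1L)
    right <- left + d
    span <- max(left - margin, 1L):min(right + margin, lens[ctg])
    if (any(occupied[[ctg]][span])) next
    occupied[[ctg]][span] <- TRUE
    mid <- (left + right) %/% 2L
    pstart <- mid - g %/% 2L
    truth[[i]] <- data.frame(
      contig = genome$contigs[ctg], left = left, right = right,
      spacing = d, gap = g, protected_start = pstart,
      protected_end = pstart + g, midpoint = mid,
      occupancy = config$occupancy)
    # suppress accessibility inside the protected gap (1-based index = pos+1)
    acc[[ctg]][(pstart + 1L):(pstart + g)] <-
      acc[[ctg]][(pstart + 1L):(pstart + g)] * config$protection_factor
    i <- i + 1L
  }
  truth <- if (config$n_sites > 0L) do.call(rbind, truth) else
    data.frame(contig = character(0), left = integer(0), right = integer(0),
               spacing = integer(0), gap = integer(0),
               protected_start = integer(0), protected_end = integer(0),
               midpoint = integer(0), occupancy = numeric(0))
  draw_background <- function() {
    lapply(genome$contigs, function(ctg) {
      as.integer(rnb(length(acc[[ctg]]), config$depth * acc[[ctg]],
                     config$dispersion))
    })
  }
  make_profile <- function(label, rep_id, spikes) {
    counts <- draw_background()
    names(counts) <- genome$contigs
    if (spikes && config$occupancy > 0 && nrow(truth) > 0L) {
      for (r in seq_len(nrow(truth))) {
        ctg <- truth$contig[r]
        for (pos in c(truth$left[r], truth$right[r])) {
          nreads <- rnb(1L, config$occupancy, config$dispersion)
          if (nreads == 0L) next
          at <- rep(pos, nreads)
          if (config$jitter_spikes) {
            at <- at + sample(c(-1L, 0L, 1L), nreads, replace = TRUE)
            at <- pmin(pmax(at, 0L), genome$lengths[[ctg]] - 1L)
          }
          tab <- table(at)
          idx <- as.integer(names(tab)) + 1L
          counts[[ctg]][idx] <- counts[[ctg]][idx] + as.integer(tab)
        }
      }
    }
    cleavage_profile(counts, genome, label = label, replicate = rep_id)
  }
  tf <- lapply(seq_len(config$n_tf), function(r)
    make_profile("tf", r, spikes = TRUE))
  control <- lapply(seq_len(config$n_control), function(r)
    make_profile("control", r, spikes = FALSE))
  structure(list(tf = tf, control = control, truth = truth, genome = genome,
                 accessibility = acc, config = config),
            class = "sim_result")
}

#' Score called sites against simulation truth
#'
#' A truth site is recovered iff some called site's midpoint lies within
#' `tolerance` bp of the truth midpoint; matching is greedy nearest-first and
#' one-to-one. A called site matching no truth midpoint is a false discovery.
#' With no calls the false-discovery proportion is undefined and reported as 0
#' with `fdp_defined = FALSE`.
#'
#' @param called data.frame with `contig` and `midpoint` (e.g. from
#'   [call_doublets()]).
#' @param truth truth data.frame from [simulate_tracks()].
#' @param tolerance matching tolerance in bp (default 10).
#' @return list: `sensitivity`, `fdp`, `n_truth`, `n_called`, `n_matched`,
#'   `fdp_defined`.
#' @export
score_recovery <- function(called, truth, tolerance = 10L) {
  stopifnot(tolerance >= 0)
  n_truth <- nrow(truth); n_called <- nrow(called)
  if (n_called == 0L) {
    return(list(sensitivity = if (n_truth > 0) 0 else NA_real_, fdp = 0,
                n_truth = n_truth, n_called = 0L, n_matched = 0L,
                fdp_defined = FALSE))
  }
  pairs <- NULL
  for (t in seq_len(n_truth)) {
    same <- which(called$contig == truth$contig[t])
    if (!length(same)) next
    dist <- abs(called$midpoint[same] - truth$midpoint[t])
    hit <- dist <= tolerance
    if (any(hit)) {
      pairs <- rbind(pairs, data.frame(truth = t, call = same[hit],
                                       dist = dist[hit]))
    }
  }
  matched_t <- logical(n_truth); matched_c <- logical(n_called)
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs$dist), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      t <- pairs$truth[r]; cl <- pairs$call[r]
      if (!matched_t[t] && !matched_c[cl]) {
        matched_t[t] <- TRUE; matched_c[cl] <- TRUE
      }
    }
  }
  list(sensitivity = if (n_truth > 0) mean(matched_t) else NA_real_,
       fdp = mean(!matched_c), n_truth = n_truth, n_called = n_called,
       n_matched = sum(matched_t), fdp_defined = TRUE)
}

#' Write simulated tracks and truth to disk
#'
#' Emits one bedGraph of raw counts per replicate, a truth BED of protected
#' intervals (named by site, score = spacing), a chrom.sizes file, and a JSON
#' echo of the configuration.
#'
#' @param sim a [simulate_tracks()] result.
#' @param dir output directory (created if needed).
#' @param format `"bedgraph"` (per-base count tracks, default) or `"sam"`
#'   (minimal single-end alignments exercising [extract_cleavage()]).
#' @return character vector of written paths, invisibly.
#' @export
write_sim <- function(sim, dir, format = c("bedgraph", "sam")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  cs <- file.path(dir, "sim.chrom.sizes")
  writeLines(sprintf("%s\t%d", sim$genome$contigs, sim$genome$lengths), cs)
  paths <- c(paths, cs)
  emit <- function(profile, stem) {
    if (format == "bedgraph") {
      p <- file.path(dir, paste0(stem, ".bedgraph"))
      write_bedgraph(profile, p, sim$genome)
    } else {
      p <- file.path(dir, paste0(stem, ".sam"))
      write_profile_sam(profile, p)
    }
    p
  }
  for (i in seq_along(sim$tf)) {
    paths <- c(paths, emit(sim$tf[[i]], sprintf("tf_rep%d", i)))
  }
  for (i in seq_along(sim$control)) {
    paths <- c(paths, emit(sim$control[[i]], sprintf("control_rep%d", i)))
  }
  truth_bed <- file.path(dir, "truth.bed")
  if (nrow(sim$truth)) {
    write_bed(data.frame(contig = sim$truth$contig,
                         start = sim$truth$protected_start,
                         end = sim$truth$protected_end,
                         name = sprintf("site_%d", seq_len(nrow(sim$truth))),
                         score = sim$truth$spacing),
              truth_bed, sim$genome)
  } else writeLines(character(0), truth_bed)
  cfg <- file.path(dir, "sim_config.json")
  jsonlite::write_json(unclass(sim$config), cfg, auto_unbox = TRUE)
  invisible(c(paths, truth_bed, cfg))
}

# minimal single-end SAM: one 25 bp read per cleavage event, alternating
# strand, placed so the 5'-most sequenced base is the event base
write_profile_sam <- function(profile, path) {
  genome <- profile$genome
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", genome$contigs, genome$lengths),
             con)
  rid <- 0L
  rlen <- 25L
  for (ctg in genome$contigs) {
    v <- profile$counts[[ctg]]
    nz <- which(v > 0)
    len <- genome$lengths[[ctg]]
    recs <- character(0)
    for (p1 in nz) {           # p1 is 1-based event position
      k <- v[p1]
      for (j in seq_len(k)) {
        rid <- rid + 1L
        # use a minus-strand read when the plus-strand read would overrun
        if (p1 + rlen - 1L <= len) {
          recs <- c(recs, sprintf(
            "read%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
            rid, ctg, p1, rlen, strrep("A", rlen)))
        } else {
          recs <- c(recs, sprintf(
            "read%d\t16\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
            rid, ctg, p1 - rlen + 1L, rlen, strrep("A", rlen)))
        }
      }
    }
    if (length(recs)) writeLines(recs, con)
  }
  invisible(path)
}
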
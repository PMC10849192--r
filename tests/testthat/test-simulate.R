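# small fast configuration used by most cases
small_cfg <- function(seed = 42L, n_sites = 6L, ...) {
  sim_config(genome_length = 30000L, n_contigs = 1L, n_sites = n_sites,
             smooth_bp = 100L, seed = seed, ...)
}

test_that("simulation is deterministic given the seed", {
  a <- simulate_tracks(small_cfg())
  b <- simulate_tracks(small_cfg())
  expect_identical(a$truth, b$truth)
  expect_identical(a$tf[[2]]$counts, b$tf[[2]]$counts)
  expect_identical(a$control[[3]]$counts, b$control[[3]]$counts)
  d <- simulate_tracks(small_cfg(seed = 43L))
  expect_false(identical(a$tf[[1]]$counts, d$tf[[1]]$counts))
})

test_that("truth geometry matches the configuration", {
  sim <- simulate_tracks(small_cfg())
  tr <- sim$truth
  expect_equal(nrow(tr), 6L)
  expect_equal(tr$right - tr$left, tr$spacing)
  expect_true(all(tr$spacing >= 15 & tr$spacing <= 50))
  expect_true(all(tr$gap >= 8 & tr$gap <= 12))
  expect_true(all(tr$protected_end - tr$protected_start == tr$gap))
  expect_true(all(tr$left >= 0 &
                    tr$right < sim$genome$lengths[tr$contig]))
  # planted sites respect the anti-chaining exclusion margin
  mids <- sort(tr$midpoint)
  expect_true(all(diff(mids) > 50))
})

test_that("limiting case: huge occupancy, zero background", {
  sim <- simulate_tracks(sim_config(
    genome_length = 5000L, n_contigs = 1L, n_sites = 1L, spacing = 30L,
    occupancy = 500, depth = 0, dispersion = 0, n_tf = 1L, n_control = 1L,
    seed = 3L))
  tfc <- sim$tf[[1]]$counts[[1]]
  nz <- which(tfc > 0) - 1L
  expect_length(nz, 2L)
  expect_equal(diff(nz), 30L)
  expect_equal(nz[1], sim$truth$left)
  expect_equal(sum(sim$control[[1]]$counts[[1]]), 0)
})

test_that("null construction: occupancy 0 gives control-like TF tracks", {
  sim <- simulate_tracks(small_cfg(occupancy = 0, n_sites = 3L))
  n_tf <- vapply(sim$tf, function(p) p$n, 0)
  n_ct <- vapply(sim$control, function(p) p$n, 0)
  # identically distributed: totals within 5 sd of NB total
  expected <- sim$config$depth * sum(unlist(sim$accessibility))
  sdev <- sqrt(expected * (1 + sim$config$dispersion * 1))
  expect_true(all(abs(c(n_tf, n_ct) - expected) < 5 * sdev * 3))
})

test_that("expected control read count tracks depth x accessibility", {
  cfg <- sim_config(genome_length = 50000L, n_contigs = 1L, n_sites = 0L,
                    depth = 0.4, dispersion = 0.1, n_tf = 1L,
                    n_control = 8L, seed = 9L)
  sim <- simulate_tracks(cfg)
  expected <- cfg$depth * sum(unlist(sim$accessibility))
  totals <- vapply(sim$control, function(p) p$n, 0)
  se <- sqrt(expected * (1 + cfg$dispersion)) # per-replicate scale
  expect_lt(abs(mean(totals) - expected), 3 * se / sqrt(length(totals)) + se)
})

test_that("score_recovery conventions", {
  truth <- data.frame(contig = "sim_1", midpoint = c(100L, 500L, 900L))
  exact <- data.frame(contig = "sim_1", midpoint = c(100L, 500L, 900L))
  sc <- score_recovery(exact, truth, 10L)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$fdp, 0)

  none <- exact[0, ]
  sc0 <- score_recovery(none, truth, 10L)
  expect_equal(sc0$sensitivity, 0)
  expect_equal(sc0$fdp, 0)
  expect_false(sc0$fdp_defined)

  far <- data.frame(contig = "sim_1", midpoint = c(150L, 550L))
  scf <- score_recovery(far, truth, 10L)
  expect_equal(scf$sensitivity, 0)
  expect_equal(scf$fdp, 1)

  # greedy one-to-one: two calls near one truth site -> one match, one false
  dup <- data.frame(contig = "sim_1", midpoint = c(99L, 101L))
  scd <- score_recovery(dup, truth, 10L)
  expect_equal(scd$n_matched, 1L)
  expect_equal(scd$fdp, 0.5)
})

test_that("SAM emission path reproduces the exact cleavage profile", {
  sim <- simulate_tracks(sim_config(genome_length = 4000L, n_contigs = 1L,
                                    n_sites = 2L, depth = 0.05,
                                    n_tf = 1L, n_control = 1L,
                                    smooth_bp = 50L, seed = 12L))
  dir <- tempfile()
  paths <- write_sim(sim, dir, format = "sam")
  g <- read_chrom_sizes(file.path(dir, "sim.chrom.sizes"))
  expect_equal(g$contigs, sim$genome$contigs)
  prof <- extract_cleavage(file.path(dir, "tf_rep1.sam"), g)
  expect_equal(prof$counts[[1]], sim$tf[[1]]$counts[[1]])
  # truth BED round-trips
  bed <- read_bed(file.path(dir, "truth.bed"))
  expect_equal(nrow(bed), 2L)
  expect_equal(bed$start, sort(sim$truth$protected_start))
})

test_that("bedGraph emission matches the tracks", {
  sim <- simulate_tracks(sim_config(genome_length = 3000L, n_contigs = 1L,
                                    n_sites = 1L, depth = 0.1, n_tf = 1L,
                                    n_control = 1L, smooth_bp = 50L,
                                    seed = 5L))
  dir <- tempfile()
  write_sim(sim, dir, format = "bedgraph")
  v <- read_bedgraph(file.path(dir, "control_rep1.bedgraph"), sim$genome)
  expect_equal(v[[1]], as.numeric(sim$control[[1]]$counts[[1]]))
})
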
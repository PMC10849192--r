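smoothed_from_values <- function(values, raw = list(), w = 3L, s = 2L) {
  lens <- vapply(values, length, 1L)
  g <- genome_index(names(values), lens)
  mt <- mean_track_from_values(g, values)
  profs <- lapply(seq_along(raw), function(i)
    cleavage_profile(raw[[i]], g, label = "s", replicate = i))
  smooth_track(mt, profs, w = w, s = s)
}

test_that("smoothing windows follow the 3 bp / 2 bp grid", {
  sm <- smoothed_from_values(list(c1 = c(1, 2, 3, 0, 0)),
                             raw = list(list(c1 = c(1L, 2L, 3L, 0L, 0L))))
  expect_equal(sm$contigs$c1$centers, c(1L, 3L))
  expect_equal(sm$contigs$c1$mean_cpm, c(2, 1))
  expect_equal(unname(sm$contigs$c1$raw[, 1]), c(6L, 3L))

  # constant track: every window mean equals the constant
  smc <- smoothed_from_values(list(c1 = rep(2.5, 11)))
  expect_true(all(smc$contigs$c1$mean_cpm == 2.5))

  # contig shorter than the window is skipped with a warning
  expect_warning(
    sms <- smoothed_from_values(list(c1 = c(1, 2), c2 = c(1, 2, 3, 4, 5))),
    "shorter than window")
  expect_null(sms$contigs$c1)
  expect_equal(sms$contigs$c2$centers, c(1L, 3L))
})

test_that("genome_baseline uses the actual genome-wide track mean", {
  g <- tiny_genome(c(c1 = 1000))
  v <- numeric(1000); v[1:10] <- 1e5  # sums to 1e6
  mt <- mean_track_from_values(g, list(c1 = v))
  expect_equal(genome_baseline(mt), 3 * 1e6 / 1000)
  # averaging unequal-depth replicates: sum deviates from 1e6
  v2 <- v * 0.8
  mt2 <- mean_track_from_values(g, list(c1 = v2))
  expect_equal(genome_baseline(mt2), 3 * sum(v2) / 1000)
  expect_equal(genome_baseline(mt2, multiplier = 5), 5 * sum(v2) / 1000)
})

test_that("local maxima rules: strict inequality, plateaus, edges", {
  # means [0,5,3,8,2] on the window grid via per-base construction is
  # awkward; drive find_local_maxima through a hand-built smoothed track
  fake <- function(means) {
    structure(list(contigs = list(c1 = list(
      centers = seq.int(1L, by = 2L, length.out = length(means)),
      mean_cpm = means,
      raw = matrix(integer(0), nrow = length(means), ncol = 0))),
      genome = genome_index("c1", 2 * length(means) + 1), w = 3L, s = 2L,
      samples = character(0)), class = "smoothed_track")
  }
  mx <- find_local_maxima(fake(c(0, 5, 3, 8, 2)), threshold = 1)
  expect_equal(mx$mean_cpm, c(5, 8))
  # plateau: no maxima under the strict rule
  expect_equal(nrow(find_local_maxima(fake(c(0, 8, 8, 2)), 0,
                                      plateau = "none")), 0L)
  # default keep-left keeps the left edge of an exact tie
  mk <- find_local_maxima(fake(c(0, 8, 8, 2)), 0)
  expect_equal(mk$center, 3L)
  # left edge window can be a maximum
  me <- find_local_maxima(fake(c(5, 1, 1)), threshold = 1)
  expect_equal(me$center, 1L)
  # threshold filters
  expect_equal(nrow(find_local_maxima(fake(c(0, 5, 3, 8, 2)), 6)), 1L)
})

test_that("smooth + maxima agree with the brute-force oracle", {
  set.seed(123)
  for (i in 1:25) {
    n <- sample(50:400, 1)
    v <- rexp(n) * rbinom(n, 1, 0.3)
    g <- genome_index("c1", n)
    mt <- mean_track_from_values(g, list(c1 = v))
    thr <- runif(1, 0, 1.5)
    sm <- smooth_track(mt, list())
    mx <- find_local_maxima(sm, thr)
    expect_equal(mx$center, oracle_maxima(v, threshold = thr))
  }
})

test_that("maxima are monotone in threshold and shift-equivariant", {
  set.seed(9)
  n <- 300
  v <- rexp(n) * rbinom(n, 1, 0.25)
  g <- genome_index("c1", n)
  sm <- smooth_track(mean_track_from_values(g, list(c1 = v)), list())
  prev <- NULL
  for (thr in c(0, 0.2, 0.5, 1, 2)) {
    cur <- find_local_maxima(sm, thr)$center
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  # translate by 2 bp (one step): centers shift by 2
  v2 <- c(0, 0, v)
  g2 <- genome_index("c1", n + 2)
  sm2 <- smooth_track(mean_track_from_values(g2, list(c1 = v2)), list())
  m1 <- find_local_maxima(sm, 0.1)$center
  m2 <- find_local_maxima(sm2, 0.1)$center
  # interior maxima must shift exactly; edge windows may differ
  expect_true(all((m1[m1 > 1 & m1 < n - 2] + 2) %in% m2))
})
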
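cond33 <- c(rep("tf", 3), rep("control", 3))

test_that("size factors implement median-of-ratios", {
  m <- matrix(c(10, 20, 30, 60, 5, 10), ncol = 2, byrow = TRUE)
  sf <- size_factors(m)
  # hand oracle: ratios col2/col1 all exactly 2 -> factors prop to (1, 2)
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(exp(mean(log(sf))), 1)

  ident <- cbind(c(5, 9, 2), c(5, 9, 2))
  expect_equal(size_factors(ident), c(1, 1))

  expect_error(size_factors(matrix(0, 3, 2)), "all-zero")
  # no all-positive row: library-size fallback with warning
  m2 <- rbind(c(10, 0), c(0, 10))
  expect_warning(sf2 <- size_factors(m2), "library-size")
  expect_equal(sf2, c(1, 1))
})

test_that("scaling one sample scales its factor and leaves log2FC invariant", {
  set.seed(5)
  m <- matrix(rnbinom(200 * 6, mu = 50, size = 10) + 1L, ncol = 6)
  sf1 <- size_factors(m)
  m2 <- m
  m2[, 1] <- m2[, 1] * 3L
  sf2 <- size_factors(m2)
  expect_equal(sf2[1] / sf1[1] / (sf2[2] / sf1[2]), 3, tolerance = 1e-12)
  # normalized condition means (and their ratio) are exactly invariant; the
  # GLM coefficient is not, because the fit pools raw counts weighted by
  # their information, so only the mean-based quantities are asserted exactly
  r1 <- nb_wald_test(m, cond33, sf = sf1, dispersions = rep(0.1, nrow(m)))
  r2 <- nb_wald_test(m2, cond33, sf = sf2, dispersions = rep(0.1, nrow(m)))
  scale1 <- r2$base_mean_tf[1] / r1$base_mean_tf[1] # common sf rescaling
  expect_equal(r2$base_mean_tf, r1$base_mean_tf * scale1, tolerance = 1e-10)
  expect_equal(r2$base_mean_control, r1$base_mean_control * scale1,
               tolerance = 1e-10)
  expect_equal(log2(r2$base_mean_tf / r2$base_mean_control),
               log2(r1$base_mean_tf / r1$base_mean_control),
               tolerance = 1e-10)
})

test_that("benjamini_hochberg matches the hand rule and stats::p.adjust", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(c(0.5, NA, 0.01)),
               c(0.5, NA, 0.02))
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(2:50, 1))^2
    expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"))
  }
  # monotone in the sorted order
  p <- runif(100)
  adj <- benjamini_hochberg(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("dispersion estimates hit the floor/oracle simulation bands", {
  set.seed(21)
  # Poisson rows (true dispersion 0): mean estimate < 0.05
  mu <- exp(runif(1000, log(5), log(50)))
  pois <- matrix(rpois(1000 * 6, rep(mu, 6)), nrow = 1000)
  d <- estimate_dispersion(pois, rep(1, 6), cond33)
  expect_lt(mean(d), 0.05)
  # NB dispersion 0.2: median estimate within [0.1, 0.4]
  mu2 <- exp(runif(2000, log(10), log(100)))
  nb <- matrix(rnbinom(2000 * 6, mu = rep(mu2, 6), size = 5), nrow = 2000)
  d2 <- estimate_dispersion(nb, rep(1, 6), cond33)
  expect_gt(median(d2), 0.1)
  expect_lt(median(d2), 0.4)
  # zero within-condition variance -> floor
  flat <- rbind(c(5, 5, 5, 2, 2, 2), c(8, 9, 7, 2, 2, 3))
  df <- estimate_dispersion(flat, rep(1, 6), cond33, floor = 1e-8)
  expect_equal(df[1], 1e-8)
  # no replication error
  expect_error(estimate_dispersion(cbind(1, 2), c(1, 1), c("tf", "control")),
               "replication")
})

# independent exact-NB likelihood-ratio oracle: ML means by 1-d optimization
oracle_nb_lrt_p <- function(k_tf, k_ctrl, alpha) {
  ll <- function(k, mu) sum(dnbinom(k, mu = mu, size = 1 / alpha, log = TRUE))
  fit1 <- function(k) {
    optimize(function(m) -ll(k, m), c(1e-6, max(k) * 3 + 10))$objective
  }
  full <- -(fit1(k_tf) + fit1(k_ctrl))
  null <- -fit1(c(k_tf, k_ctrl))
  pchisq(2 * (full - null), df = 1, lower.tail = FALSE)
}

test_that("Wald test matches the worked examples", {
  m <- rbind(strong = c(400, 420, 390, 10, 12, 9),
             weak = c(30, 28, 33, 10, 11, 9),
             null = c(20, 21, 19, 20, 21, 19))
  disp <- rep(0.05, 3)
  res <- nb_wald_test(m, cond33, sf = rep(1, 6), dispersions = disp)
  # log2(403.33/10.33) = 5.29
  expect_equal(res["strong", "log2fc"], log2(403.3333 / 10.3333),
               tolerance = 0.01)
  expect_true(res["strong", "retained"])
  expect_lt(res["strong", "padj"], 1e-4)
  expect_lt(oracle_nb_lrt_p(m[1, 1:3], m[1, 4:6], disp[1]), 1e-4)
  # log2(30.33/10) = 1.60 < 1.7: never retained, whatever the p
  expect_equal(res["weak", "log2fc"], log2(30.3333 / 10), tolerance = 0.01)
  expect_false(res["weak", "retained"])
  # identical conditions: log2FC ~ 0, not retained
  expect_equal(res["null", "log2fc"], 0, tolerance = 1e-6)
  expect_false(res["null", "retained"])
})

test_that("boundary rows use the LRT fallback and behave sensibly", {
  m <- rbind(zero = c(60, 70, 55, 0, 0, 0),
             near = c(43, 71, 42, 0, 0, 1),
             flat = c(3, 2, 4, 3, 2, 4))
  res <- nb_wald_test(m, cond33, sf = rep(1, 6),
                      dispersions = rep(0.1, 3))
  expect_equal(unname(res$test), c("lrt", "lrt", "wald"))
  expect_lt(res["zero", "padj"], 1e-4)
  expect_lt(res["near", "padj"], 1e-4)
  expect_true(all(res[c("zero", "near"), "retained"]))
  # moderated reporting keeps the all-zero fold change finite
  expect_true(is.finite(res["zero", "log2fc"]))
  # adjusted p never smaller than raw p
  expect_true(all(res$padj >= res$pvalue - 1e-15))
})

test_that("swapping condition labels negates every log2FC", {
  set.seed(8)
  m <- matrix(rnbinom(50 * 6, mu = 40, size = 8) + 1L, ncol = 6)
  disp <- rep(0.12, nrow(m))
  sf <- size_factors(m)
  r1 <- nb_wald_test(m, cond33, sf = sf, dispersions = disp)
  r2 <- nb_wald_test(m, rev(cond33), sf = sf, dispersions = disp)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-6)
})

test_that("input validation errors are raised", {
  m <- matrix(1:12, ncol = 6)
  expect_error(nb_wald_test(m, rep("tf", 6)), "control")
  expect_error(nb_wald_test(m, c("a", "b", "a", "b", "a", "b")),
               "condition")
  expect_error(nb_config(alpha = 2), "alpha")
  expect_error(benjamini_hochberg(c(0.5, 2)), "0, 1")
})
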
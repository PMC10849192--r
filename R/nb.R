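#' Configuration for the negative-binomial enrichment test
#'
#' Defaults follow the published cutoffs: windows are retained when the
#' estimated log2 fold change (TF over control) exceeds 1.7 AND the
#' BH-adjusted Wald p-value is below 1e-4.
#'
#' @param lfc_min minimum log2 fold change (default 1.7).
#' @param alpha adjusted p-value cutoff (default 1e-4).
#' @param pseudocount added to normalized condition means when reporting fold
#'   changes for rows with an all-zero condition (default 0.5); the GLM fit
#'   itself uses no pseudocount.
#' @param dispersion_floor lower bound on the dispersion estimate
#'   (default 1e-8).
#' @return list of class `nb_config`.
#' @export
nb_config <- function(lfc_min = 1.7, alpha = 1e-4, pseudocount = 0.5,
                      dispersion_floor = 1e-8) {
  stopifnot(lfc_min >= 0, alpha > 0, alpha < 1, pseudocount >= 0,
            dispersion_floor > 0)
  structure(list(lfc_min = lfc_min, alpha = alpha, pseudocount = pseudocount,
                 dispersion_floor = dispersion_floor),
            class = "nb_config")
}

#' Median-of-ratios size factors
#'
#' The standard count-normalization: each sample's factor is the median across
#' rows of its count divided by the row geometric mean, using rows where every
#' sample is positive; factors are rescaled to geometric mean 1. If no row is
#' all-positive, library-size ratios are used with a warning.
#'
#' @param counts integer matrix, rows = windows, columns = samples.
#' @return positive numeric vector, one factor per column.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all-zero count matrix")
  log_gm <- rowMeans(log(counts))
  ok <- is.finite(log_gm)
  if (any(ok)) {
    sf <- exp(apply(log(counts[ok, , drop = FALSE]) - log_gm[ok], 2, median))
  } else {
    warning("no row with all-positive counts; using library-size ratios")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("sample with zero total counts")
  }
  sf / exp(mean(log(sf)))
}

#' Per-row negative-binomial dispersion estimates
#'
#' Method-of-moments on size-factor-normalized counts, pooled across
#' conditions after centering each condition on its own mean (so true
#' enrichment does not inflate the estimate), then shrunk toward a fitted
#' mean-dispersion trend `a0 + a1/mean` and floored. The raw and trend
#' components are combined as a geometric mean on the log scale, which is the
#' lightweight analogue of the empirical-Bayes shrinkage used by standard
#' differential-count tools.
#'
#' @param counts integer matrix (windows x samples).
#' @param sf size factors from [size_factors()].
#' @param condition character/factor of length `ncol(counts)`.
#' @param floor dispersion floor (default 1e-8).
#' @return numeric vector of per-row dispersions (alpha in
#'   `Var = mu + alpha mu^2`).
#' @export
estimate_dispersion <- function(counts, sf, condition, floor = 1e-8) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (ncol(counts) < 2L) stop("no replication: need >= 2 samples")
  if (nlevels(condition) == 1L && ncol(counts) < 2L) {
    stop("no replication")
  }
  q <- sweep(counts, 2L, sf, "/")
  mu <- rowMeans(q)
  # within-condition residuals; df = n - number of conditions with samples
  resid <- q
  for (lev in levels(condition)) {
    j <- which(condition == lev)
    resid[, j] <- q[, j, drop = FALSE] - rowMeans(q[, j, drop = FALSE])
  }
  df <- ncol(counts) - nlevels(condition)
  if (df < 1L) stop("no replication: need replicates within a condition")
  v <- rowSums(resid^2) / df
  # fitted per-sample mean = its condition mean; under NB,
  # E[v] ~ mean_j(mu_j / s_j) + alpha * mean_j(mu_j^2)
  mu_fit <- q
  for (lev in levels(condition)) {
    j <- which(condition == lev)
    mu_fit[, j] <- rowMeans(q[, j, drop = FALSE])
  }
  shot <- rowMeans(sweep(mu_fit, 2L, sf, "/"))
  denom <- rowMeans(mu_fit^2)
  raw <- (v - shot) / denom
  raw[!is.finite(raw)] <- 0
  raw <- pmax(raw, floor)
  trend <- fit_dispersion_trend(mu, raw, floor)
  # MAP-style shrinkage on the log scale: 1/4 weight on the per-row moment
  # estimate (noise-floored at trend/10), 3/4 on the trend; the weights
  # reflect the large sampling variance of a 4-df variance estimate relative
  # to the trend. Rows with exactly zero within-condition variance drop to
  # the floor.
  est <- exp(log(pmax(raw, trend / 10)) / 4 + 3 * log(trend) / 4)
  est[v == 0] <- floor
  pmax(est, floor)
}

# robust least-squares fit of alpha ~ a0 + a1/mu on rows with signal;
# falls back to the median when the fit is degenerate
fit_dispersion_trend <- function(mu, raw, floor) {
  use <- which(mu > 0 & raw > floor)
  if (length(use) < 10L) {
    return(rep(max(median(raw), floor), length(mu)))
  }
  x <- 1 / mu[use]; y <- raw[use]
  for (i in 1:2) {
    fit <- stats::lm.fit(cbind(1, x), y)
    r <- fit$residuals
    keep <- abs(r) <= 4 * (stats::mad(r) + 1e-12)
    if (i == 1L && any(!keep) && sum(keep) >= 10L) {
      x <- x[keep]; y <- y[keep]
    }
  }
  a0 <- max(fit$coefficients[1L], 0)
  a1 <- max(fit$coefficients[2L], 0)
  if (a0 == 0 && a1 == 0) {
    return(rep(max(median(raw), floor), length(mu)))
  }
  pmax(a0 + a1 / pmax(mu, 1e-8), floor)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-rolled standard step-up: adjusted p are monotone and capped at 1.
#' NaN/NA p-values propagate and are excluded from the ranking.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- length(ok)
  ord <- order(p[ok], decreasing = TRUE)
  adj <- pmin(1, cummin(p[ok][ord] * m / seq.int(m, 1L)))
  out[ok[ord]] <- adj
  out
}

# NB log-likelihood at fixed dispersion alpha (Poisson limit for tiny alpha)
nb_loglik <- function(k, mu, alpha) {
  if (alpha < 1e-12) return(sum(stats::dpois(k, mu, log = TRUE)))
  sum(stats::dnbinom(k, mu = mu, size = 1 / alpha, log = TRUE))
}

# two-group NB GLM with log link and log(sf) offsets, fixed dispersion alpha.
# IRLS converges on the relative log-likelihood change (not the coefficient
# step), so rows whose MLE sits at the boundary (e.g. an all-zero control
# condition) still converge with a finite Wald statistic, matching the
# behavior of standard differential-count tools.
nb_glm_two_group <- function(k, sf, is_tf, alpha, max_iter = 100L,
                             tol = 1e-8) {
  x <- as.numeric(is_tf)
  X <- cbind(1, x)
  qn <- k / sf
  m_ctrl <- mean(qn[!is_tf]); m_tf <- mean(qn[is_tf])
  beta <- c(log(m_ctrl + 0.1), log(m_tf + 0.1) - log(m_ctrl + 0.1))
  mu_of <- function(beta) sf * exp(pmin(pmax(beta[1L] + beta[2L] * x, -30),
                                        30))
  ll <- nb_loglik(k, mu_of(beta), alpha)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- mu_of(beta)
    w <- mu / (1 + alpha * mu)
    eta <- log(mu / sf)
    z <- eta + (k - mu) / mu
    xtw <- t(X * w)
    new_beta <- tryCatch(as.numeric(solve(xtw %*% X, xtw %*% z)),
                         error = function(e) NULL)
    if (is.null(new_beta)) break
    new_beta <- pmin(pmax(new_beta, -30), 30)
    new_ll <- nb_loglik(k, mu_of(new_beta), alpha)
    # step-halve if the IRLS step overshoots
    half <- 0L
    while (new_ll < ll - 1e-12 && half < 10L) {
      new_beta <- (new_beta + beta) / 2
      new_ll <- nb_loglik(k, mu_of(new_beta), alpha)
      half <- half + 1L
    }
    done <- abs(new_ll - ll) < tol * (abs(ll) + 0.1)
    beta <- new_beta
    ll <- new_ll
    if (done) { converged <- TRUE; break }
  }
  mu <- mu_of(beta)
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  se1 <- tryCatch(sqrt(solve(info)[2L, 2L]), error = function(e) NA_real_)
  list(b0 = beta[1L], b1 = beta[2L], se1 = se1, converged = converged,
       loglik = ll)
}

# intercept-only NB fit with offsets (1-d Newton on b0), for the LRT null
nb_glm_null <- function(k, sf, alpha, max_iter = 100L, tol = 1e-10) {
  b0 <- log((sum(k) / sum(sf)) + 0.1)
  for (it in seq_len(max_iter)) {
    mu <- sf * exp(pmin(pmax(b0, -30), 30))
    grad <- sum((k - mu) / (1 + alpha * mu))
    hess <- -sum(mu * (1 + alpha * k) / (1 + alpha * mu)^2)
    step <- -grad / hess
    if (!is.finite(step)) break
    b0 <- pmin(pmax(b0 + step, -30), 30)
    if (abs(step) < tol) break
  }
  mu <- sf * exp(pmin(pmax(b0, -30), 30))
  list(b0 = b0, loglik = nb_loglik(k, mu, alpha))
}

#' Negative-binomial Wald test of TF enrichment over control
#'
#' Per window, fits a two-group NB generalized linear model with log link and
#' size-factor offsets at the row's dispersion, and tests the condition
#' coefficient (log fold change of TF over control) with a two-sided Wald
#' test against the normal reference. For rows where either condition totals
#' at most one count the Wald statistic degenerates (Hauck-Donner effect:
#' the standard error diverges as the fitted mean approaches the zero
#' boundary), so the likelihood-ratio test against the intercept-only model
#' is used instead (`test = "lrt"` in the output). P-values are BH-adjusted
#' across all tested rows and windows are flagged as retained when
#' `log2FC > lfc_min` and `padj < alpha`. Non-convergent rows get `p = 1` and
#' are never retained. For rows with an all-zero condition the reported
#' `log2fc` is moderated with a pseudocount on the normalized means to keep
#' it finite.
#'
#' @param counts integer matrix (windows x samples); give it rownames to keep
#'   window ids.
#' @param condition vector with values `"tf"` / `"control"` per column.
#' @param sf size factors (default: computed by [size_factors()]).
#' @param dispersions per-row dispersions (default: [estimate_dispersion()]).
#' @param config an [nb_config()].
#' @return data.frame with per-row `base_mean_tf`, `base_mean_control`
#'   (size-factor-normalized condition means), `log2fc`, `se_log2fc`, `pvalue`,
#'   `padj`, `converged`, `retained`.
#' @export
nb_wald_test <- function(counts, condition, sf = NULL, dispersions = NULL,
                         config = nb_config()) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  if (!all(condition %in% c("tf", "control"))) {
    stop("condition must be 'tf' or 'control'")
  }
  if (!any(condition == "tf") || !any(condition == "control")) {
    stop("need at least one TF and one control sample")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, sf, condition,
                                       floor = config$dispersion_floor)
  }
  is_tf <- condition == "tf"
  nr <- nrow(counts)
  q <- sweep(counts, 2L, sf, "/")
  bm_tf <- rowMeans(q[, is_tf, drop = FALSE])
  bm_ct <- rowMeans(q[, !is_tf, drop = FALSE])
  log2fc <- se <- pval <- rep(NA_real_, nr)
  conv <- rep(FALSE, nr)
  test <- rep("wald", nr)
  # Wald statistics collapse when a condition sits at or near the zero
  # boundary (Hauck-Donner effect); fall back to the likelihood-ratio test
  # for rows where either condition totals <= 1 count.
  tot_tf <- rowSums(counts[, is_tf, drop = FALSE])
  tot_ct <- rowSums(counts[, !is_tf, drop = FALSE])
  boundary <- pmin(tot_tf, tot_ct) <= 1
  ln2 <- log(2)
  for (i in seq_len(nr)) {
    fit <- nb_glm_two_group(counts[i, ], sf, is_tf, dispersions[i])
    conv[i] <- fit$converged && is.finite(fit$se1)
    log2fc[i] <- fit$b1 / ln2
    se[i] <- fit$se1 / ln2
    if (!conv[i]) {
      pval[i] <- 1
    } else if (boundary[i]) {
      null <- nb_glm_null(counts[i, ], sf, dispersions[i])
      lrt <- max(2 * (fit$loglik - null$loglik), 0)
      pval[i] <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
      test[i] <- "lrt"
    } else {
      pval[i] <- 2 * stats::pnorm(-abs(fit$b1 / fit$se1))
    }
  }
  # moderated fold change for reporting when a condition is all zero
  degenerate <- bm_ct == 0 | bm_tf == 0
  if (any(degenerate)) {
    pc <- config$pseudocount
    log2fc[degenerate] <- log2((bm_tf[degenerate] + pc) /
                                 (bm_ct[degenerate] + pc))
  }
  padj <- benjamini_hochberg(pval)
  out <- data.frame(
    base_mean_tf = bm_tf, base_mean_control = bm_ct,
    log2fc = log2fc, se_log2fc = se, dispersion = dispersions,
    test = test, pvalue = pval, padj = padj, converged = conv,
    retained = conv & log2fc > config$lfc_min & padj < config$alpha)
  rownames(out) <- rownames(counts)
  out
}
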
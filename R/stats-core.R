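#' Pearson correlation with degenerate-input checking
#'
#' Sample Pearson correlation between two equal-length sequences. Unlike
#' [stats::cor()], zero-variance input is an error rather than `NA`, because
#' every downstream use (homotopy matrices, gradient-profile scoring) treats
#' a flat time course or profile as a defect of the input, not a value.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop_contract("x and y must have equal length")
  if (length(x) < 3L) stop_contract("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop_contract("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_degenerate("zero-variance input to pearson_corr")
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Partial correlation controlling for confounds
#'
#' Correlation of the least-squares residuals of `x` and `y` after regressing
#' out the confound columns plus an intercept. Used to control motion in the
#' cross-hemisphere correlation matrices.
#'
#' @param x,y numeric vectors of equal length.
#' @param confounds numeric vector or matrix of confound time courses
#'   (one column per confound).
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_corr <- function(x, y, confounds) {
  confounds <- as.matrix(confounds)
  n <- length(x)
  if (length(y) != n || nrow(confounds) != n)
    stop_contract("x, y and confounds must have matching length")
  # constant confounds are absorbed by the intercept
  keep <- apply(confounds, 2, function(v) stats::sd(v) > 0)
  design <- cbind(1, confounds[, keep, drop = FALSE])
  if (qr(design)$rank < ncol(design))
    stop_contract("confound design (with intercept) is rank deficient")
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    stop_degenerate("zero-variance residual after confound regression")
  pearson_corr(rx, ry)
}

#' Fisher Z transform and its inverse
#'
#' `z = atanh(r)` with `r` clipped to `1 - eps` in magnitude first, so the
#' unit diagonal of a self-correlation matrix maps to a large finite value
#' rather than infinity. Correlations are always Fisher transformed before
#' they are averaged or differenced, and transformed back for display.
#'
#' @param r correlation value(s), `|r| <= 1`.
#' @param eps clipping tolerance (default `1e-7`).
#' @return Fisher Z value(s).
#' @export
fisher_z <- function(r, eps = 1e-7) {
  if (any(abs(r) > 1 + 1e-12)) stop_contract("|r| must be <= 1")
  r <- pmax(-1, pmin(1, r))
  atanh(pmax(-(1 - eps), pmin(1 - eps, r)))
}

#' @rdname fisher_z
#' @param z Fisher Z value(s).
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Bootstrap test of a mean difference across participants
#'
#' Resamples participants with replacement `n_boot` times; the two-tailed p
#' is twice the fraction of pseudosample means whose sign differs from the
#' observed mean (capped at 1). A zero count of sign flips is reported as
#' `p < 2 / n_boot`; an observed mean of exactly zero is flagged degenerate
#' and returns p = 1. The 95% interval is the 2.5/97.5 percentile interval
#' of the pseudosample means, with no bias correction.
#'
#' @param per_participant_diffs numeric vector, one difference per
#'   participant (Fisher-Z units when the inputs are correlations).
#' @param n_boot number of pseudosamples (default 10000).
#' @param seed integer RNG seed.
#' @return A `bootstrap_result` list: `mean_diff`, `ci_low`, `ci_high`,
#'   `p_two_tailed`, `p_report` (printable form), `n_boot`, `seed`,
#'   `degenerate`.
#' @export
bootstrap_mean_difference <- function(per_participant_diffs, n_boot = 10000L,
                                      seed = 1L) {
  d <- per_participant_diffs
  if (length(d) < 1L) stop_contract("need at least one participant")
  if (n_boot < 1L) stop_contract("n_boot must be >= 1")
  obs <- mean(d)
  n <- length(d)
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(d[idx], nrow = n_boot))
  })
  ci <- unname(stats::quantile(means, c(0.025, 0.975), type = 7))
  if (obs == 0) {
    res <- list(mean_diff = obs, ci_low = ci[1], ci_high = ci[2],
                p_two_tailed = 1, p_report = "degenerate (mean = 0)",
                n_boot = as.integer(n_boot), seed = as.integer(seed),
                degenerate = TRUE)
  } else {
    flips <- mean(sign(means) != sign(obs))
    p <- min(1, 2 * flips)
    rep <- if (p == 0) sprintf("< %g", 2 / n_boot) else sprintf("%g", p)
    res <- list(mean_diff = obs, ci_low = ci[1], ci_high = ci[2],
                p_two_tailed = p, p_report = rep,
                n_boot = as.integer(n_boot), seed = as.integer(seed),
                degenerate = FALSE)
  }
  class(res) <- "bootstrap_result"
  res
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap mean difference: M = %.4f, 95%% CI [%.4f, %.4f], p %s (n_boot = %d)\n",
              x$mean_diff, x$ci_low, x$ci_high,
              if (x$p_two_tailed == 0) x$p_report else sprintf("= %s", x$p_report),
              x$n_boot))
  invisible(x)
}

#' Exact two-tailed binomial test
#'
#' Two-tailed p under `Binomial(trials, p0)` using the doubling rule:
#' `p = min(1, 2 * min(P(X <= s), P(X >= s)))`, computed from exact binomial
#' mass (no normal approximation). With 13 successes in 14 trials at
#' `p0 = 0.5` this gives `30/16384`, printed as 0.002.
#'
#' @param successes,trials non-negative counts, `successes <= trials`.
#' @param p0 null success probability in (0, 1).
#' @return A `binomial_test_result` list: `successes`, `trials`, `p0`,
#'   `p_two_tailed`.
#' @export
binomial_two_tailed <- function(successes, trials, p0 = 0.5) {
  if (trials < 1 || successes < 0 || successes > trials)
    stop_contract("require 0 <= successes <= trials, trials >= 1")
  if (p0 <= 0 || p0 >= 1) stop_contract("p0 must be in (0, 1)")
  lower <- stats::pbinom(successes, trials, p0)
  upper <- stats::pbinom(successes - 1, trials, p0, lower.tail = FALSE)
  res <- list(successes = as.integer(successes), trials = as.integer(trials),
              p0 = p0, p_two_tailed = min(1, 2 * min(lower, upper)))
  class(res) <- "binomial_test_result"
  res
}

#' @export
print.binomial_test_result <- function(x, ...) {
  cat(sprintf("binomial test: %d/%d vs p0 = %g, two-tailed p = %.4g\n",
              x$successes, x$trials, x$p0, x$p_two_tailed))
  invisible(x)
}

# one Guttman (SMACOF) majorization pass for metric MDS
guttman_step <- function(conf, delta, d) {
  n <- nrow(conf)
  b <- matrix(0, n, n)
  pos <- d > 1e-12
  b[pos] <- -delta[pos] / d[pos]
  diag(b) <- 0
  diag(b) <- -rowSums(b)
  (b %*% conf) / n
}

mds_distances <- function(conf) as.matrix(stats::dist(conf))

#' Kruskal stress-1 of a configuration against input dissimilarities
#' @param delta symmetric dissimilarity matrix.
#' @param conf points-by-dims configuration.
#' @return Stress-1 value (0 = perfect).
#' @export
kruskal_stress1 <- function(delta, conf) {
  d <- mds_distances(conf)
  lt <- lower.tri(delta)
  denom <- sum(delta[lt]^2)
  if (denom == 0) return(0)
  sqrt(sum((delta[lt] - d[lt])^2) / denom)
}

#' Metric multidimensional scaling by stress majorization
#'
#' SMACOF-style metric MDS: minimizes raw stress by iterated Guttman
#' transforms from several seeded starts (the first start is the classical
#' scaling solution, the rest seeded Gaussian configurations) and reports the
#' best configuration with its Kruskal stress-1. Deterministic given `seed`.
#'
#' @param dissimilarity square symmetric nonnegative matrix, zero diagonal.
#' @param n_dims embedding dimensionality (default 2).
#' @param seed integer seed for the random restarts.
#' @param n_init number of restarts (default 8).
#' @param max_iter,tol iteration cap and relative stress convergence
#'   tolerance per restart.
#' @return An `mds_embedding` list: `coordinates` (points x n_dims),
#'   `stress` (Kruskal stress-1), `dissimilarity_in`.
#' @export
mds_embed <- function(dissimilarity, n_dims = 2L, seed = 1L, n_init = 8L,
                      max_iter = 300L, tol = 1e-9) {
  delta <- as.matrix(dissimilarity)
  if (nrow(delta) != ncol(delta)) stop_contract("dissimilarity must be square")
  if (max(abs(delta - t(delta))) > 1e-8) stop_contract("dissimilarity must be symmetric")
  if (any(delta < 0)) stop_contract("dissimilarity must be nonnegative")
  if (any(abs(diag(delta)) > 1e-12)) stop_contract("diagonal must be zero")
  delta <- (delta + t(delta)) / 2
  n <- nrow(delta)
  if (n == 1L) {
    out <- list(coordinates = matrix(0, 1, n_dims), stress = 0,
                dissimilarity_in = delta)
    class(out) <- "mds_embedding"
    return(out)
  }

  run_from <- function(conf) {
    s_old <- kruskal_stress1(delta, conf)
    for (it in seq_len(max_iter)) {
      conf <- guttman_step(conf, delta, mds_distances(conf))
      s_new <- kruskal_stress1(delta, conf)
      if (s_old - s_new < tol * max(s_old, 1e-300)) { s_old <- s_new; break }
      s_old <- s_new
    }
    list(conf = conf, stress = s_old)
  }

  inits <- vector("list", n_init)
  cmd <- suppressWarnings(stats::cmdscale(delta, k = min(n_dims, n - 1L)))
  if (ncol(cmd) < n_dims) cmd <- cbind(cmd, matrix(0, n, n_dims - ncol(cmd)))
  inits[[1L]] <- cmd
  scale0 <- max(delta)
  for (i in seq_len(n_init - 1L)) {
    inits[[i + 1L]] <- with_seed(child_seed(seed, i),
                                 matrix(stats::rnorm(n * n_dims, sd = scale0), n, n_dims))
  }
  fits <- lapply(inits, run_from)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  conf <- sweep(best$conf, 2, colMeans(best$conf))
  out <- list(coordinates = conf, stress = best$stress,
              dissimilarity_in = delta)
  class(out) <- "mds_embedding"
  out
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("MDS embedding: %d points in %d dims, Kruskal stress-1 = %.4f\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress))
  invisible(x)
}
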
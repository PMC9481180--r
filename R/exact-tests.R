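#' @rdname mann_whitney
#' @format NULL
#' @keywords internal
test_result <- function(statistic, p_value, method, n, mode_used) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method, n = n,
         mode_used = mode_used),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result>", x$method, "(", x$mode_used, ") statistic =",
      signif(x$statistic, 6), ", p =", signif(x$p_value, 6), "\n")
  invisible(x)
}

# Distribution of the x-group rank sum over all C(N, n) subsets of the
# pooled midranks (doubled to integers). Returns list(support, prob);
# support values are doubled rank sums.
ranksum_distribution <- function(ranks2, n) {
  N <- length(ranks2)
  smax <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n)])
  # f[k+1, s+1] = number of k-subsets with doubled rank sum s
  f <- matrix(0, nrow = n + 1, ncol = smax + 1)
  f[1, 1] <- 1
  for (r in ranks2) {
    kmax <- n
    for (k in kmax:1) {
      nz <- which(f[k, ] > 0)
      if (length(nz)) {
        tgt <- nz + r
        keep <- tgt <= smax + 1
        f[k + 1, tgt[keep]] <- f[k + 1, tgt[keep]] + f[k, nz[keep]]
      }
    }
  }
  counts <- f[n + 1, ]
  support <- which(counts > 0) - 1
  list(support = support, prob = counts[support + 1] / sum(counts[support + 1]))
}

two_sided_from_cdf <- function(support, prob, obs) {
  lo <- sum(prob[support <= obs + 1e-9])
  hi <- sum(prob[support >= obs - 1e-9])
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test of a location difference between two independent samples.
#' In exact mode the permutation distribution of the rank sum over all
#' `C(n+m, n)` group assignments of the pooled values is computed by a
#' shift-algorithm count over (doubled) midranks, so ties are handled
#' exactly; the two-sided p is twice the smaller tail, capped at 1. In
#' approximate mode a normal approximation with tie and continuity
#' correction is used. `auto` selects exact when `n*m <= 5000`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"exact"`, `"approx"`, or `"auto"`.
#' @return A `test_result` with `statistic` = the Mann-Whitney U of `x`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_x <- sum(r[seq_len(n)])
  u <- w_x - n * (n + 1) / 2
  use_exact <- mode == "exact" || (mode == "auto" && n * m <= 5000)
  if (use_exact) {
    dist <- ranksum_distribution(round(2 * r), n)
    p <- two_sided_from_cdf(dist$support, dist$prob, 2 * w_x)
    mode_used <- "exact"
  } else {
    N <- n + m
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    mu <- n * m / 2
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    mode_used <- "approx"
  }
  test_result(u, max(p, .Machine$double.xmin), "mann_whitney",
              c(n = n, m = m), mode_used)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided one-sample signed-rank test. Zero differences are dropped
#' (all-zero input is an error). In exact mode the null distribution of the
#' positive-rank sum over all `2^n` sign assignments is computed by
#' polynomial convolution over the (doubled) midranks of `|d|`; `auto`
#' selects exact for `n <= 15`.
#'
#' @param diffs Numeric vector of paired differences.
#' @param mode `"exact"`, `"approx"`, or `"auto"`.
#' @return A `test_result` with `statistic` = positive-rank sum `W+`.
#' @export
wilcoxon_signed_rank <- function(diffs, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(diffs) == 0) stop("no differences supplied")
  d <- diffs[diffs != 0]
  if (length(d) == 0) stop("all differences are zero; signed-rank test undefined")
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  use_exact <- mode == "exact" || (mode == "auto" && n <= 15)
  if (use_exact) {
    r2 <- round(2 * r)
    # coefficient vector over doubled W+: product of (1 + z^r2_i)/2
    coef <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), coef[seq_len(length(coef) - ri)])
      coef <- (coef + shifted) / 2
    }
    support <- which(coef > 0) - 1
    p <- two_sided_from_cdf(support, coef[support + 1], 2 * w_plus)
    mode_used <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    mode_used <- "approx"
  }
  test_result(w_plus, max(p, .Machine$double.xmin), "wilcoxon_signed_rank",
              n, mode_used)
}

# Pooled-score Z statistic for every outcome table at fixed group sizes.
# Rows of the conceptual 2x2 are success/failure, columns the two groups.
barnard_z_matrix <- function(n1, n2) {
  y1 <- 0:n1
  y2 <- 0:n2
  p1 <- outer(y1 / n1, rep(1, n2 + 1))
  p2 <- outer(rep(1, n1 + 1), y2 / n2)
  pbar <- outer(y1, y2, `+`) / (n1 + n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  z[!is.finite(z)] <- 0  # pooled proportion 0 or 1: no evidence either way
  z
}

#' Barnard unconditional exact test for a 2x2 table
#'
#' Exact unconditional test of equality of two binomial proportions.
#' Outcomes are ordered by the absolute pooled-score statistic `|Z|`; for a
#' given nuisance success probability `pi` the tail probability is the sum
#' of binomial-product probabilities over outcome tables at the fixed group
#' sizes with `|Z| >= |Z_obs|`, and the reported p-value is the supremum
#' over `pi` in (0, 1), located on a 1000-point grid and refined by local
#' univariate optimization.
#'
#' @param table 2x2 matrix (or object coercible to one): rows =
#'   success/failure, columns = the two groups; column sums are the group
#'   sizes and must be positive.
#' @param grid_points Number of nuisance-grid points (default 1000).
#' @return A `test_result` with `statistic` = observed pooled-score Z.
#' @export
barnard_test <- function(table, grid_points = 1000) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("barnard_test requires a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("table must hold nonnegative counts")
  n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2])
  if (n1 == 0 || n2 == 0) stop("both group sizes must be positive")
  x1 <- tab[1, 1]; x2 <- tab[1, 2]
  z <- barnard_z_matrix(n1, n2)
  z_obs <- z[x1 + 1, x2 + 1]
  mask <- abs(z) >= abs(z_obs) - 1e-12
  tail_prob <- function(pi) {
    pr <- outer(stats::dbinom(0:n1, n1, pi), stats::dbinom(0:n2, n2, pi))
    sum(pr[mask])
  }
  grid <- seq_len(grid_points) / (grid_points + 1)
  vals <- vapply(grid, tail_prob, numeric(1))
  i <- which.max(vals)
  lo <- if (i > 1) grid[i - 1] else 1e-9
  hi <- if (i < length(grid)) grid[i + 1] else 1 - 1e-9
  ref <- stats::optimize(tail_prob, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  p <- min(1, max(vals[i], ref$objective))
  test_result(z_obs, max(p, .Machine$double.xmin), "barnard",
              c(n1 = n1, n2 = n2), "exact")
}
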
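#' Wilcoxon signed-rank test with normal-approximation effect size
#'
#' Two-sided paired signed-rank test on a vector of pre/post differences.
#' Zero differences are dropped and ties receive mid-ranks (Wilcoxon's
#' original treatment). The p value is exact when at most 25 non-zero
#' differences remain and their absolute values are tie-free (null
#' signed-rank distribution), or when at most 12 remain even under ties
#' (full enumeration of sign assignments on the observed mid-ranks);
#' otherwise the normal approximation with continuity and tie correction
#' is used. The standardized statistic Z from
#' the normal approximation is always computed, giving the effect size
#' r = Z / sqrt(n) conventional in rank-based meta-analysis.
#'
#' @param deltas Numeric vector of paired differences (post - pre).
#' @return List with `statistic` (V, sum of positive ranks), `n_used`
#'   (non-zero differences), `z`, `p_value`, `effect_r`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_signed_rank <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  d <- deltas[deltas != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, n_used = 0L, z = 0, p_value = 1,
                effect_r = 0, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(list(statistic = v, n_used = n, z = 0, p_value = 1,
                effect_r = 0, method = "degenerate"))
  }
  # continuity-corrected Z toward the mean
  cc <- sign(v - mu) * 0.5
  z <- (v - mu - cc) / sqrt(sigma2)
  if (v == mu) z <- 0
  tie_free <- all(ties == 1L)
  if (n <= 25L && tie_free) {
    p <- min(1, 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n)))
    method <- "exact"
  } else if (n <= 12L) {
    # exact even under tied |d|: enumerate the 2^n sign assignments on the
    # observed mid-ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(v_all <= v), mean(v_all >= v)))
    method <- "exact"
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = v, n_used = n, z = z, p_value = p,
       effect_r = z / sqrt(n), method = method)
}

#' Wilcoxon rank-sum (Mann-Whitney) test with effect size
#'
#' Two-sided unpaired comparison of two groups. Exact p when both groups
#' have at most 25 observations and the pooled values are tie-free;
#' otherwise normal approximation with continuity and tie correction.
#' Effect size r = Z / sqrt(n1 + n2). Positive `z` (and `r`) means `y`
#' tends to be larger than `x`.
#'
#' @param x,y Numeric vectors for the two groups.
#' @return List with `statistic` (Mann-Whitney U of `y` over `x`), `n1`,
#'   `n2`, `z`, `p_value`, `effect_r`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  # U counts pairs where y exceeds x (ties half-weighted)
  u <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = u, n1 = n1, n2 = n2, z = 0, p_value = 1,
                effect_r = 0, method = "degenerate"))
  }
  cc <- sign(u - mu) * 0.5
  z <- (u - mu - cc) / sqrt(sigma2)
  if (u == mu) z <- 0
  tie_free <- all(ties == 1L)
  if (max(n1, n2) <= 25L && tie_free) {
    p <- min(1, 2 * min(pwilcox(u, n2, n1), 1 - pwilcox(u - 1, n2, n1)))
    method <- "exact"
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = u, n1 = n1, n2 = n2, z = z, p_value = p,
       effect_r = z / sqrt(n), method = method)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: sort p ascending, p_adj[(i)] =
#' min over j >= i of m * p[(j)] / j, capped at 1, returned in input order.
#'
#' @param p_values Numeric vector of raw p values in \[0, 1\].
#' @return Adjusted p values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
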
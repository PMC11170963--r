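# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (enumeration, direct formulas) and must stay
# independent of the package implementation they check.

# Random composition (Dirichlet via gamma draws).
random_composition <- function(k, alpha = 1) {
  g <- rgamma(k, shape = alpha)
  g / sum(g)
}

# Random sparse composition with a given fraction of zeros.
random_sparse_composition <- function(k, zero_frac = 0.3) {
  x <- rgamma(k, shape = 1)
  x[sample.int(k, floor(zero_frac * k))] <- 0
  if (sum(x) == 0) x[1] <- 1
  x / sum(x)
}

# Brute-force dissimilarity formulas, written term by term.
oracle_bray <- function(p, q) sum(abs(p - q)) / sum(p + q)
oracle_hellinger <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
}
oracle_spearman <- function(p, q) {
  (1 - cor(rank(p), rank(q))) / 2
}
oracle_jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  term <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  0.5 * term(p) + 0.5 * term(q)
}

# Exact two-sided signed-rank p by full enumeration of the 2^n sign
# assignments, using the observed ranks of |d| (mid-ranks under ties).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided rank-sum p by enumerating all C(n1+n2, n1) group
# assignments; statistic is the Mann-Whitney U of the second group.
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  combos <- utils::combn(n1 + n2, n2)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n2 * (n2 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# BH step-up straight from the definition: p_adj[(i)] = min_{j>=i} m p_(j)/j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# PERMANOVA pieces recomputed independently from the definition.
oracle_permanova_stats <- function(d, labels) {
  n <- ncol(d)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  a <- length(unique(labels))
  list(r2 = ss_between / ss_total,
       f = (ss_between / (a - 1)) / (ss_within / (n - a)))
}

# Exact PERMANOVA p over every distinct relabeling (small n only).
enum_permanova_p <- function(d, labels) {
  n <- length(labels)
  lev <- unique(labels)
  stopifnot(length(lev) == 2)
  n1 <- sum(labels == lev[1])
  f_obs <- oracle_permanova_stats(d, labels)$f
  combos <- utils::combn(n, n1)
  f_all <- apply(combos, 2, function(idx) {
    lab <- rep(lev[2], n)
    lab[idx] <- lev[1]
    oracle_permanova_stats(d, lab)$f
  })
  mean(f_all >= f_obs - 1e-12)
}

# Graph property oracle from the adjacency matrix of a simple graph.
oracle_graph_props <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  m <- sum(adj) / 2
  triangles <- sum(diag(adj %*% adj %*% adj)) / 6
  triples <- sum(deg * (deg - 1) / 2)
  list(
    n_nodes = n, n_edges = m,
    density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
    connectivity = 2 * m / n,
    clustering = if (triples > 0) 3 * triangles / triples else 0
  )
}

# Newman modularity of a given node partition, from the definition
# Q = sum_c (e_c / m - (d_c / 2m)^2).
oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  q <- 0
  for (g in unique(membership)) {
    idx <- which(membership == g)
    e_c <- sum(adj[idx, idx]) / 2
    d_c <- sum(rowSums(adj)[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Small synthetic cohort shortcut used by several tests: one arm.
one_arm_config <- function(n_subjects, n_species, affected_fraction,
                           effect_sd, seed, subject_sd = 2, noise_sd = 0.3,
                           ...) {
  synthetic_config(
    n_subjects = n_subjects, n_species = n_species, n_genes = 5,
    arm_effects = list(drug = list(affected_fraction = affected_fraction,
                                   effect_sd = effect_sd)),
    subject_sd = subject_sd, noise_sd = noise_sd, seed = seed, ...
  )
}
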
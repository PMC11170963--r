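test_that("single-pair dissimilarities match closed forms and bounds", {
  # worked values
  expect_equal(bray_curtis(c(0.7, 0.3), c(0.5, 0.5)), 0.2)
  expect_equal(hellinger(c(1, 0), c(0.5, 0.5)), sqrt(1 - sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(spearman_dissimilarity(3:1, 1:3), 1)
  expect_equal(jensen_shannon(c(0.5, 0.5), c(0.9, 0.1)),
               oracle_jsd(c(0.5, 0.5), c(0.9, 0.1)), tolerance = 1e-12)

  # identities
  p <- c(0.2, 0.3, 0.5)
  expect_equal(bray_curtis(p, p), 0)
  expect_equal(hellinger(p, p), 0)
  expect_equal(spearman_dissimilarity(p, p), 0)
  expect_equal(jensen_shannon(p, p), 0)

  # disjoint supports
  a <- c(0.5, 0.5, 0, 0)
  b <- c(0, 0, 0.3, 0.7)
  expect_equal(bray_curtis(a, b), 1)
  expect_equal(hellinger(a, b), 1)
  expect_equal(jensen_shannon(a, b), log(2), tolerance = 1e-12)

  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(spearman_dissimilarity(c(1, 1, 1), c(1, 2, 3)),
               "rank variance")
  expect_error(spearman_dissimilarity(c(1, 2), c(2, 1)), ">= 3")
})

test_that("spearman dissimilarity equals rank-then-Pearson on random pairs", {
  set.seed(8)
  for (i in 1:50) {
    p <- rgamma(20, 0.7)
    q <- rgamma(20, 0.7)
    expect_equal(spearman_dissimilarity(p, q),
                 (1 - cor(rank(p), rank(q))) / 2, tolerance = 1e-12)
  }
})

test_that("distance_matrix equals looped pairwise calls for every metric", {
  set.seed(9)
  m <- matrix(rgamma(15 * 8, 0.5), nrow = 15,
              dimnames = list(sprintf("sp%d", 1:15), sprintf("S%d", 1:8)))
  m[sample(length(m), 30)] <- 0
  tab <- to_relative(abundance_table(m, "counts"))
  pair_fun <- list(bray_curtis = bray_curtis, hellinger = hellinger,
                   spearman = spearman_dissimilarity, jsd = jensen_shannon)
  for (metric in names(pair_fun)) {
    dm <- distance_matrix(tab, metric)
    expect_identical(attr(dm, "metric"), metric)
    expect_equal(unname(diag(dm)), rep(0, 8))
    expect_lt(max(abs(dm - t(dm))), 1e-12)
    f <- pair_fun[[metric]]
    for (i in 1:7) {
      for (j in (i + 1):8) {
        expect_equal(dm[i, j], f(tab$values[, i], tab$values[, j]),
                     tolerance = 1e-12,
                     label = sprintf("%s[%d,%d]", metric, i, j))
      }
    }
  }
})

test_that("Bray-Curtis matrix agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(10)
  m <- matrix(rgamma(12 * 6, 1), nrow = 12,
              dimnames = list(sprintf("sp%d", 1:12), sprintf("S%d", 1:6)))
  tab <- to_relative(abundance_table(m, "counts"))
  dm <- distance_matrix(tab, "bray_curtis")
  ref <- as.matrix(vegan::vegdist(t(tab$values), method = "bray"))
  expect_equal(unclass(dm), ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PERMANOVA reproduces the SS decomposition and the enumeration p", {
  # two well-separated 3-sample clusters in composition space
  m <- cbind(
    matrix(rep(c(8, 1, 1, 1), 3), ncol = 3) + matrix(runif(12, 0, 0.2), 4),
    matrix(rep(c(1, 1, 1, 8), 3), ncol = 3) + matrix(runif(12, 0, 0.2), 4)
  )
  dimnames(m) <- list(sprintf("sp%d", 1:4), sprintf("S%d", 1:6))
  tab <- to_relative(abundance_table(m, "counts"))
  dm <- distance_matrix(tab, "bray_curtis")
  labels <- rep(c("pre", "post"), each = 3)

  res <- permanova(dm, labels, n_perm = 9999, seed = 11)
  oracle <- oracle_permanova_stats(unclass(dm), labels)
  expect_equal(res$r_squared, oracle$r2, tolerance = 1e-12)
  expect_equal(res$pseudo_f, oracle$f, tolerance = 1e-12)
  # full enumeration over the 20 label splits vs the permutation estimate
  p_exact <- enum_permanova_p(unclass(dm), labels)
  expect_lt(abs(res$p_value - p_exact), 0.02)
  expect_gt(res$r_squared, 0.5)

  # determinism at a fixed seed
  res2 <- permanova(dm, labels, n_perm = 9999, seed = 11)
  expect_identical(res$p_value, res2$p_value)
})

test_that("PERMANOVA matches vegan::adonis2 on a random distance matrix", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(rgamma(20 * 10, 0.6), nrow = 20,
              dimnames = list(sprintf("sp%d", 1:20), sprintf("S%d", 1:10)))
  tab <- to_relative(abundance_table(m, "counts"))
  dm <- distance_matrix(tab, "bray_curtis")
  labels <- rep(c("pre", "post"), each = 5)
  res <- permanova(dm, labels, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(dm) ~ g,
                        data = data.frame(g = labels), permutations = 99)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA degenerate and invariance properties hold", {
  # identical samples: every distance 0 -> R2 = 0
  m <- matrix(rep(c(3, 2, 1), 6), nrow = 3,
              dimnames = list(sprintf("sp%d", 1:3), sprintf("S%d", 1:6)))
  dm <- distance_matrix(to_relative(abundance_table(m, "counts")),
                        "bray_curtis")
  res <- permanova(dm, rep(c("a", "b"), 3), n_perm = 49, seed = 2)
  expect_equal(res$r_squared, 0)

  # consistent sample permutation leaves R2 and F unchanged
  set.seed(13)
  m <- matrix(rgamma(10 * 8, 1), nrow = 10,
              dimnames = list(sprintf("sp%d", 1:10), sprintf("S%d", 1:8)))
  dm <- distance_matrix(to_relative(abundance_table(m, "counts")), "jsd")
  labels <- setNames(rep(c("pre", "post"), 4), colnames(dm))
  perm <- sample(colnames(dm))
  r1 <- permanova(dm, labels, n_perm = 9, seed = 3)
  r2 <- permanova(dm[perm, perm], labels[perm], n_perm = 9, seed = 3)
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-12)
  expect_equal(r1$pseudo_f, r2$pseudo_f, tolerance = 1e-12)

  expect_error(permanova(dm, c(rep("a", 7), "b"), n_perm = 9), ">= 2 samples")
})

test_that("fingerprint assignment recovers subjects when fingerprints persist", {
  sim <- simulate_cohort(one_arm_config(30, 80, 0, 0, seed = 14))
  design <- build_paired_design(sim$metadata, 84)
  dm <- distance_matrix(sim$species, "bray_curtis")
  fr <- fingerprint_assignment(dm, design)
  expect_gte(fr$accuracy, 0.9)
  expect_false(fr$degenerate)
  expect_equal(nrow(fr$assignments), 30L)
  # rank of the true baseline is 1 exactly for the correct assignments
  expect_true(all(fr$assignments$rank_true[fr$assignments$correct] == 1L))
  expect_equal(fr$accuracy, mean(fr$assignments$correct))
})

test_that("strong perturbation destroys the fingerprint", {
  sim <- simulate_cohort(one_arm_config(50, 100, 0.3, 2, seed = 15))
  design <- build_paired_design(sim$metadata, 84)
  dm <- distance_matrix(sim$species, "bray_curtis")
  fr <- fingerprint_assignment(dm, design)
  expect_lte(fr$accuracy, 0.5)
})

test_that("fingerprint ties break lexicographically and degenerate cases flag", {
  # construct a distance matrix with an exact tie between two baselines
  ids <- c("A_0", "B_0", "A_1", "B_1")
  d <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d["A_1", "A_0"] <- d["A_0", "A_1"] <- 0.1
  d["A_1", "B_0"] <- d["B_0", "A_1"] <- 0.1  # tie for A's post sample
  d["B_1", "B_0"] <- d["B_0", "B_1"] <- 0.2
  meta <- cohort_metadata(data.frame(
    sample_id = ids, subject_id = c("A", "B", "A", "B"),
    arm = "drug", timepoint_day = c(0L, 0L, 84L, 84L)))
  design <- build_paired_design(meta, 84)
  fr <- fingerprint_assignment(d, design)
  a_row <- fr$assignments[fr$assignments$post_sample_id == "A_1", ]
  expect_true(a_row$tie)
  expect_equal(a_row$assigned_subject, "A")  # lexicographic tie-break

  solo <- design[design$subject_id == "A", ]
  fr1 <- fingerprint_assignment(d, solo)
  expect_true(fr1$degenerate)
  expect_equal(fr1$accuracy, 1)
})
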
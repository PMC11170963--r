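test_that("percentage change and responder stratification follow their rules", {
  expect_equal(percent_change(8, 6), -25)
  expect_equal(percent_change(7.1, 7.1), 0)
  # typical trial-level means: 8.20 % -> 6.36 % HbA1c
  expect_equal(percent_change(8.20, 6.36), -22.44, tolerance = 0.01)
  expect_error(percent_change(0, 5), "percentage change")

  r <- stratify_responders(c(a = -30, b = -20, c = -10, d = 0))
  expect_setequal(r$subject_id[r$class == "HR"], c("a", "b"))
  expect_setequal(r$subject_id[r$class == "LR"], c("c", "d"))
  expect_equal(unname(attr(r, "counts")), c(2L, 2L))

  # odd n: the median subject goes to LR, splitting 2/3
  r5 <- stratify_responders(c(s1 = -40, s2 = -25, s3 = -15, s4 = -5, s5 = 2))
  expect_identical(r5$class[r5$subject_id == "s3"], "LR")
  expect_equal(unname(attr(r5, "counts")), c(2L, 3L))

  # subject order does not change the classes
  shuffled <- stratify_responders(c(s4 = -5, s1 = -40, s5 = 2, s3 = -15,
                                    s2 = -25))
  m <- merge(r5, shuffled, by = "subject_id")
  expect_identical(m$class.x, m$class.y)

  # duplicate median values are assigned deterministically to LR
  rd <- stratify_responders(c(x1 = -10, x2 = -10, x3 = -10, x4 = -30))
  expect_identical(rd$class[rd$subject_id %in% c("x1", "x2", "x3")],
                   rep("LR", 3))
  expect_error(stratify_responders(c(1, 1, 1, 1)), "identical")
  expect_error(stratify_responders(c(1, 2, 3)), ">= 4")
})

test_that("partial Spearman screen recovers direct effects and kills mediated ones", {
  set.seed(27)
  n <- 200
  covars <- data.frame(age = rnorm(n, 52, 8), sex = rbinom(n, 1, 0.5),
                       bmi = rnorm(n, 26, 3))
  f_direct <- rnorm(n)
  response <- 2 * f_direct + rnorm(n, 0, 0.3)
  feats <- rbind(direct = f_direct, noise = rnorm(n))
  res <- partial_spearman_screen(feats, response, covars)
  expect_gte(res$partial_rho[res$feature_id == "direct"], 0.95)
  expect_true(res$significant[res$feature_id == "direct"])

  # full mediation: feature and response share only a covariate
  set.seed(28)
  n <- 500
  z <- rnorm(n)
  feats <- rbind(mediated = z + rnorm(n, 0, 0.1))
  response <- 3 * z + rnorm(n, 0, 0.1)
  res <- partial_spearman_screen(feats, response,
                                 data.frame(confounder = z))
  expect_lt(abs(res$partial_rho[1]), 0.1)
  expect_false(res$significant[1])

  # constant features are excluded, not guessed
  feats <- rbind(flat = rep(1, 50), live = rnorm(50))
  res <- partial_spearman_screen(feats, rnorm(50), NULL)
  expect_true(res$excluded[res$feature_id == "flat"])
  expect_false(res$significant[res$feature_id == "flat"])

  # significance requires BOTH |rho| > 0.3 and p < 0.05
  expect_true(all(!res$significant |
                    (abs(res$partial_rho) > 0.3 & res$p_value < 0.05)))
  expect_equal(count_significant_features(res), sum(res$significant))
  expect_equal(count_significant_features(res[0, ]), 0L)
})

test_that("null features rarely pass the screen", {
  set.seed(29)
  n <- 100
  feats <- matrix(rnorm(60 * n), nrow = 60,
                  dimnames = list(sprintf("f%02d", 1:60), NULL))
  res <- partial_spearman_screen(feats, rnorm(n),
                                 data.frame(age = rnorm(n)))
  expect_gte(mean(!res$significant), 0.95)
})

test_that("elastic net selects planted features and reports the refit R2", {
  # pure-noise features: little variance should be claimed
  set.seed(30)
  feats <- matrix(rnorm(50 * 200), nrow = 50,
                  dimnames = list(sprintf("f%02d", 1:50), NULL))
  res0 <- elasticnet_variance_explained(feats, rnorm(200), seed = 1)
  expect_lte(res0$r_squared, 0.1)

  # three planted features at true R2 = 0.4
  set.seed(31)
  n <- 200
  feats <- matrix(rnorm(50 * n), nrow = 50,
                  dimnames = list(sprintf("f%02d", 1:50), NULL))
  y <- colSums(feats[1:3, ]) + rnorm(n, 0, sqrt(4.5))
  res <- elasticnet_variance_explained(feats, y, seed = 2)
  expect_true(all(c("f01", "f02", "f03") %in% res$selected_features))
  expect_lt(abs(res$r_squared - 0.4), 0.1)

  # degenerate: response equals one feature exactly
  y2 <- feats["f07", ]
  res2 <- suppressWarnings(elasticnet_variance_explained(feats, y2, seed = 3))
  expect_true("f07" %in% res2$selected_features)
  expect_gte(res2$r_squared, 0.99)

  # determinism at a fixed seed
  res3 <- elasticnet_variance_explained(feats, y, seed = 2)
  expect_identical(res$selected_features, res3$selected_features)
  expect_identical(res$r_squared, res3$r_squared)
  expect_error(elasticnet_variance_explained(feats[, 1:25], y[1:25],
                                             cv_folds = 30), "cv_folds")
})

test_that("responder logistic odds ratios collapse to the 2x2 cross-product", {
  # HR: 10 exposed / 5 unexposed; LR: 5 exposed / 10 unexposed -> OR 4
  feature <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  classes <- c(rep("HR", 15), rep("LR", 15))
  res <- responder_logistic(feature, classes)
  expect_false(res$separation)
  expect_equal(res$odds_ratio, 4, tolerance = 1e-6)
  expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)

  # perfect separation is flagged, not reported as a huge OR
  sep_feature <- c(rnorm(10, 10), rnorm(10, -10))
  sep_classes <- rep(c("HR", "LR"), each = 10)
  res_sep <- responder_logistic(sep_feature, sep_classes)
  expect_true(res_sep$separation)
  expect_true(is.na(res_sep$odds_ratio))

  expect_error(responder_logistic(rep(1, 10), rep(c("HR", "LR"), 5)),
               "constant")
  expect_error(responder_logistic(rnorm(10), rep("HR", 10)), "non-empty")
})

test_that("GEE equals OLS with independent clusters and finds planted slopes", {
  set.seed(32)
  n <- 40
  x <- rnorm(n)
  y <- 1.5 + 2 * x + rnorm(n)
  g <- gee_longitudinal(x, y, subjects = paste0("s", 1:n))
  ols <- coef(lm(y ~ x))
  expect_equal(g$estimate, unname(ols), tolerance = 1e-6)
  expect_true(attr(g, "converged"))

  # planted within-subject association across two timepoints
  signs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    nsub <- 40
    subj <- rep(paste0("p", 1:nsub), each = 2)
    subj_int <- rep(rnorm(nsub, 0, 2), each = 2)
    feat <- rnorm(2 * nsub)
    clin <- subj_int + 0.8 * feat + rnorm(2 * nsub, 0, 0.5)
    g <- gee_longitudinal(feat, clin, subj)
    sign(g$estimate[g$term == "feature"])
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)

  expect_error(gee_longitudinal(rep(1, 10), rnorm(10), rep(1:5, 2)),
               "zero variance")
})
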
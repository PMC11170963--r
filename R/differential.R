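#' Paired differential abundance of species or genes
#'
#' Per-feature two-sided Wilcoxon signed-rank test on per-subject
#' post-minus-pre deltas, for one arm's paired design. Species are tested on
#' the centered log-ratio scale (`transform = "clr"`: the table is closed to
#' relative abundances and CLR-transformed first); functional genes are
#' tested on their RPKM values directly (`transform = "rpkm_raw"`). Effect
#' sizes are `r = Z / sqrt(n_pairs)` from the normal approximation, and BH
#' adjustment spans all features tested in the call. A feature's direction is
#' `increased`/`decreased` only when its BH-adjusted p falls below `alpha`,
#' with the sign taken from the median delta.
#'
#' @param tab An `abundance_table` (species or genes).
#' @param design A `paired_design` (use one arm's subset for per-arm tests,
#'   or pass `arm` to subset here).
#' @param transform `"clr"` or `"rpkm_raw"`.
#' @param alpha Significance level on BH-adjusted p values.
#' @param arm Optional arm name to subset the design.
#' @param pseudocount CLR pseudocount policy, see [clr_transform()].
#' @return Data frame of class `feature_test_result`: `feature_id`,
#'   `n_pairs`, `statistic`, `z_value`, `effect_r`, `median_delta`,
#'   `direction`, `p_raw`, `p_bh`.
#' @export
paired_feature_tests <- function(tab, design,
                                 transform = c("clr", "rpkm_raw"),
                                 alpha = 0.05, arm = NULL,
                                 pseudocount = "half-min") {
  stopifnot(inherits(tab, "abundance_table"), inherits(design, "paired_design"))
  transform <- match.arg(transform)
  if (!is.null(arm)) {
    design <- design[design$arm %in% arm, , drop = FALSE]
  }
  if (nrow(design) < 3L) stop("need >= 3 pairs", call. = FALSE)
  vals <- if (transform == "clr") {
    clr_transform(to_relative(tab), pseudocount = pseudocount)
  } else {
    tab$values
  }
  missing_s <- setdiff(c(design$pre_sample_id, design$post_sample_id),
                       colnames(vals))
  if (length(missing_s)) {
    stop("table lacks sample(s): ", paste(head(missing_s, 5), collapse = ", "),
         call. = FALSE)
  }
  deltas <- vals[, design$post_sample_id, drop = FALSE] -
    vals[, design$pre_sample_id, drop = FALSE]
  rows <- lapply(seq_len(nrow(deltas)), function(i) {
    d <- deltas[i, ]
    wt <- wilcoxon_signed_rank(d)
    data.frame(
      feature_id = rownames(deltas)[i], n_pairs = length(d),
      statistic = wt$statistic, z_value = wt$z,
      effect_r = if (wt$n_used > 0) wt$z / sqrt(length(d)) else 0,
      median_delta = median(d), p_raw = wt$p_value,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$p_bh <- bh_adjust(res$p_raw)
  res$direction <- ifelse(
    res$p_bh < alpha,
    ifelse(res$median_delta > 0, "increased", "decreased"),
    "ns"
  )
  res <- res[, c("feature_id", "n_pairs", "statistic", "z_value", "effect_r",
                 "median_delta", "direction", "p_raw", "p_bh")]
  class(res) <- c("feature_test_result", "data.frame")
  res
}

#' Cross-arm comparison of post-treatment samples
#'
#' Per-feature two-sided Wilcoxon rank-sum test comparing the post-treatment
#' samples of two arms (e.g. a drug alone versus the drug combined with a
#' dietary intervention). Effect size `r = Z / sqrt(n_a + n_b)`; positive `r`
#' means the feature is higher in `arm_b`. Two significance tiers are
#' flagged: `sig_bh` (BH-adjusted p < `alpha`) and `sig_raw` (raw p < 0.05),
#' plus an indicator for |r| >= 0.3, the conventional moderate-effect line.
#'
#' @param tab An `abundance_table`.
#' @param meta A `cohort_metadata`.
#' @param arm_a,arm_b Arm names to compare (direction: `r > 0` favors
#'   `arm_b`).
#' @param post_day Post-treatment day selecting the samples.
#' @param transform `"clr"` or `"rpkm_raw"` as in [paired_feature_tests()].
#' @param alpha BH significance level.
#' @param pseudocount CLR pseudocount policy.
#' @return Data frame of class `feature_test_result`: `feature_id`, `n_a`,
#'   `n_b`, `statistic`, `z_value`, `effect_r`, `direction`
#'   (`higher_in_<arm>` / `ns` at the BH tier), `p_raw`, `p_bh`, `sig_bh`,
#'   `sig_raw`, `abs_r_ge_0.3`.
#' @export
crossarm_posttreatment_tests <- function(tab, meta, arm_a, arm_b, post_day,
                                         transform = c("clr", "rpkm_raw"),
                                         alpha = 0.05,
                                         pseudocount = "half-min") {
  stopifnot(inherits(tab, "abundance_table"), inherits(meta, "cohort_metadata"))
  transform <- match.arg(transform)
  post <- meta[meta$timepoint_day == as.integer(post_day), ]
  sa <- post$sample_id[post$arm == arm_a]
  sb <- post$sample_id[post$arm == arm_b]
  if (length(sa) < 3L || length(sb) < 3L) {
    stop("need >= 3 post-treatment samples per arm", call. = FALSE)
  }
  vals <- if (transform == "clr") {
    clr_transform(to_relative(tab), pseudocount = pseudocount)
  } else {
    tab$values
  }
  missing_s <- setdiff(c(sa, sb), colnames(vals))
  if (length(missing_s)) {
    stop("table lacks sample(s): ", paste(head(missing_s, 5), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(rownames(vals), function(f) {
    wt <- wilcoxon_rank_sum(vals[f, sa], vals[f, sb])
    data.frame(
      feature_id = f, n_a = wt$n1, n_b = wt$n2, statistic = wt$statistic,
      z_value = wt$z, effect_r = wt$effect_r, p_raw = wt$p_value,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$p_bh <- bh_adjust(res$p_raw)
  res$sig_bh <- res$p_bh < alpha
  res$sig_raw <- res$p_raw < 0.05
  res$`abs_r_ge_0.3` <- abs(res$effect_r) >= 0.3
  res$direction <- ifelse(
    res$sig_bh,
    ifelse(res$effect_r > 0, paste0("higher_in_", arm_b),
           paste0("higher_in_", arm_a)),
    "ns"
  )
  class(res) <- c("feature_test_result", "data.frame")
  res
}
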
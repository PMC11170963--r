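#' Centered log-ratio transform
#'
#' Per-sample CLR on relative abundances: `y_i = ln(p_i + c) - mean_j
#' ln(p_j + c)`. The pseudocount `c` handles structural zeros; the default
#' policy `"half-min"` uses half the smallest non-zero relative abundance in
#' the whole table, one constant table-wide, so CLR values stay comparable
#' across samples.
#'
#' @param tab An `abundance_table` of relative abundances (columns summing
#'   to 1; apply [to_relative()] first if needed).
#' @param pseudocount Positive number, or the string `"half-min"`.
#' @return Numeric matrix (features x samples) of CLR values; every column
#'   sums to 0 (within floating point).
#' @export
clr_transform <- function(tab, pseudocount = "half-min") {
  stopifnot(inherits(tab, "abundance_table"))
  v <- tab$values
  if (identical(pseudocount, "half-min")) {
    pos <- v[v > 0]
    if (!length(pos)) stop("table has no positive entries", call. = FALSE)
    c0 <- min(pos) / 2
  } else {
    stop_if_not_scalar_number(pseudocount, "pseudocount")
    if (pseudocount <= 0) {
      stop("explicit pseudocount must be > 0", call. = FALSE)
    }
    c0 <- pseudocount
  }
  lg <- log(v + c0)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Species richness of one sample
#'
#' Number of features detected above a threshold (default 0: any positive
#' abundance counts).
#'
#' @param sample Non-negative numeric vector of abundances.
#' @param detection_threshold Non-negative detection limit.
#' @return Integer count.
#' @export
richness <- function(sample, detection_threshold = 0) {
  stop_if_not_scalar_number(detection_threshold, "detection_threshold")
  if (detection_threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  sum(sample > detection_threshold)
}

#' Shannon diversity of one sample (natural log)
#'
#' `H = -sum p_i ln p_i` over the positive entries, after re-normalizing
#' them to sum 1. Reported in nats.
#'
#' @param sample Non-negative numeric vector of abundances.
#' @return Shannon index in nats.
#' @export
shannon <- function(sample) {
  pos <- sample[sample > 0]
  if (!length(pos)) stop("all-zero sample has no Shannon index", call. = FALSE)
  p <- pos / sum(pos)
  -sum(p * log(p))
}

#' Per-sample alpha diversity for a whole table
#'
#' @param tab An `abundance_table`.
#' @param detection_threshold Passed to [richness()].
#' @return Data frame with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(tab, detection_threshold = 0) {
  stopifnot(inherits(tab, "abundance_table"))
  v <- tab$values
  data.frame(
    sample_id = colnames(v),
    richness = apply(v, 2, richness, detection_threshold = detection_threshold),
    shannon = apply(v, 2, shannon),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Paired pre/post test of a per-sample quantity, by arm
#'
#' For each study arm, forms per-subject deltas (post - pre) of a per-sample
#' value (e.g. richness or Shannon index) and runs the two-sided Wilcoxon
#' signed-rank test, flagging arms significant at p < 0.05. The confidence
#' interval is the t-based interval for the mean delta.
#'
#' @param values Named numeric vector, one value per sample (names are
#'   sample identifiers covering all design samples).
#' @param design A `paired_design` from [build_paired_design()].
#' @param conf_level Confidence level for the mean-delta interval.
#' @return Data frame with one row per arm: `arm`, `n_pairs`, `mean_delta`,
#'   `se_delta`, `ci_low`, `ci_high`, `p_value`, `significant`.
#' @export
paired_delta_test <- function(values, design, conf_level = 0.95) {
  stopifnot(inherits(design, "paired_design"))
  need <- c(design$pre_sample_id, design$post_sample_id)
  missing_s <- setdiff(need, names(values))
  if (length(missing_s)) {
    stop("values missing for sample(s): ",
         paste(head(missing_s, 5), collapse = ", "), call. = FALSE)
  }
  arms <- unique(design$arm)
  rows <- lapply(arms, function(a) {
    d <- design[design$arm == a, ]
    if (nrow(d) < 3L) {
      stop(sprintf("arm '%s' has %d pairs; need >= 3", a, nrow(d)),
           call. = FALSE)
    }
    delta <- values[d$post_sample_id] - values[d$pre_sample_id]
    wt <- wilcoxon_signed_rank(delta)
    n <- length(delta)
    se <- sd(delta) / sqrt(n)
    tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 1)
    data.frame(
      arm = a, n_pairs = n, mean_delta = mean(delta), se_delta = se,
      ci_low = mean(delta) - tcrit * se, ci_high = mean(delta) + tcrit * se,
      p_value = wt$p_value, significant = wt$p_value < 0.05,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
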
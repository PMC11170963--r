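#' Pairwise community dissimilarities
#'
#' The four dissimilarity measures used for community-composition contrasts
#' between paired samples:
#' \describe{
#'   \item{`bray_curtis`}{`sum|p_i - q_i| / sum(p_i + q_i)`, in \[0, 1\].}
#'   \item{`hellinger`}{`(1/sqrt(2)) * ||sqrt(p) - sqrt(q)||_2` after
#'     re-closing each vector to sum 1, in \[0, 1\].}
#'   \item{`spearman_dissimilarity`}{`(1 - rho)/2` with `rho` the Spearman
#'     rank correlation (mid-ranks for ties), scaled to \[0, 1\]. Note this
#'     rescaling changes absolute values relative to `1 - rho` but not any
#'     ranking of pairs.}
#'   \item{`jensen_shannon`}{`JSD(p, q) = KL(p||m)/2 + KL(q||m)/2` with
#'     `m = (p+q)/2`, natural log, `0 ln 0 := 0`, in \[0, ln 2\] nats
#'     (reported as the divergence, not its square root).}
#' }
#'
#' @param p,q Non-negative abundance vectors of equal length.
#' @return A single dissimilarity value.
#' @name dissimilarities
NULL

#' @rdname dissimilarities
#' @export
bray_curtis <- function(p, q) {
  check_pair(p, q)
  denom <- sum(p) + sum(q)
  if (denom <= 0) stop("both vectors are all-zero", call. = FALSE)
  sum(abs(p - q)) / denom
}

#' @rdname dissimilarities
#' @export
hellinger <- function(p, q) {
  check_pair(p, q)
  if (sum(p) <= 0 || sum(q) <= 0) {
    stop("cannot close an all-zero vector", call. = FALSE)
  }
  sp <- sqrt(p / sum(p))
  sq <- sqrt(q / sum(q))
  sqrt(sum((sp - sq)^2)) / sqrt(2)
}

#' @rdname dissimilarities
#' @export
spearman_dissimilarity <- function(p, q) {
  check_pair(p, q)
  if (length(p) < 3L) stop("need >= 3 features for rank correlation",
                           call. = FALSE)
  rp <- rank(p)
  rq <- rank(q)
  if (var(rp) == 0 || var(rq) == 0) {
    stop("zero rank variance (constant vector)", call. = FALSE)
  }
  (1 - cor(rp, rq)) / 2
}

#' @rdname dissimilarities
#' @export
jensen_shannon <- function(p, q) {
  check_pair(p, q)
  if (sum(p) <= 0 || sum(q) <= 0) {
    stop("cannot close an all-zero vector", call. = FALSE)
  }
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

check_pair <- function(p, q) {
  if (length(p) != length(q)) stop("vectors differ in length", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("negative abundances", call. = FALSE)
  invisible(NULL)
}

#' All pairwise dissimilarities of a table's samples
#'
#' @param tab An `abundance_table` (>= 2 samples).
#' @param metric One of `"bray_curtis"`, `"hellinger"`, `"spearman"`,
#'   `"jsd"`.
#' @return A `distance_matrix`: symmetric numeric matrix with zero diagonal,
#'   sample identifiers as dimnames, and the metric name in the `"metric"`
#'   attribute.
#' @export
distance_matrix <- function(tab,
                            metric = c("bray_curtis", "hellinger",
                                       "spearman", "jsd")) {
  stopifnot(inherits(tab, "abundance_table"))
  metric <- match.arg(metric)
  v <- tab$values
  n <- ncol(v)
  if (n < 2L) stop("need >= 2 samples", call. = FALSE)
  d <- switch(
    metric,
    bray_curtis = {
      cs <- colSums(v)
      if (any(cs <= 0)) stop("all-zero sample(s): ",
                             paste(colnames(v)[cs <= 0], collapse = ", "),
                             call. = FALSE)
      m <- as.matrix(dist(t(v), method = "manhattan"))
      m / outer(cs, cs, "+")
    },
    hellinger = {
      cs <- colSums(v)
      if (any(cs <= 0)) stop("all-zero sample(s): ",
                             paste(colnames(v)[cs <= 0], collapse = ", "),
                             call. = FALSE)
      s <- sqrt(sweep(v, 2, cs, "/"))
      as.matrix(dist(t(s))) / sqrt(2)
    },
    spearman = {
      if (nrow(v) < 3L) stop("need >= 3 features", call. = FALSE)
      r <- apply(v, 2, rank)
      rv <- apply(r, 2, var)
      if (any(rv == 0)) stop("zero rank variance in sample(s): ",
                             paste(colnames(v)[rv == 0], collapse = ", "),
                             call. = FALSE)
      (1 - cor(r)) / 2
    },
    jsd = {
      cs <- colSums(v)
      if (any(cs <= 0)) stop("all-zero sample(s): ",
                             paste(colnames(v)[cs <= 0], collapse = ", "),
                             call. = FALSE)
      p <- sweep(v, 2, cs, "/")
      # H(m) - (H(p)+H(q))/2 formulation, vectorized over pairs
      ent <- function(x) {
        x <- x[x > 0]
        -sum(x * log(x))
      }
      hs <- apply(p, 2, ent)
      m <- matrix(0, n, n)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          hij <- ent((p[, i] + p[, j]) / 2)
          m[i, j] <- m[j, i] <- hij - (hs[i] + hs[j]) / 2
        }
      }
      m
    }
  )
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0  # clip tiny negative round-off
  dimnames(d) <- list(colnames(v), colnames(v))
  structure(d, metric = metric, class = c("distance_matrix", "matrix", "array"))
}

#' PERMANOVA on a two-level grouping of a distance matrix
#'
#' One-way permutational multivariate analysis of variance. Sums of squares
#' follow the distance decomposition `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum over groups of (within-group pair d^2 sums) / n_group`,
#' `SS_between = SS_total - SS_within`; `R^2 = SS_between / SS_total`;
#' `pseudo-F = (SS_between/(a-1)) / (SS_within/(n-a))`. Significance by free
#' relabeling of samples: `p = (1 + #permuted F >= observed F) /
#' (1 + n_perm)`.
#'
#' @param dm A `distance_matrix` (or plain symmetric matrix with dimnames).
#' @param labels Factor-like grouping, one label per sample, in `dm` column
#'   order (or named by sample).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @return A `permanova_result` list: `r_squared`, `pseudo_f`, `p_value`,
#'   `n_permutations`, `seed`, `ss` (the decomposition).
#' @export
permanova <- function(dm, labels, n_perm = 999, seed = 1) {
  d <- as.matrix(dm)
  n <- ncol(d)
  if (!is.null(names(labels))) labels <- labels[colnames(d)]
  labels <- as.character(labels)
  if (length(labels) != n || anyNA(labels)) {
    stop("labels must cover every sample in the distance matrix",
         call. = FALSE)
  }
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("each group needs >= 2 samples; got: ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
         call. = FALSE)
  }
  a <- length(tab)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_for <- function(lab) {
    sw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- d2[idx, idx, drop = FALSE]
      sw <- sw + sum(sub[upper.tri(sub)]) / length(idx)
    }
    sw
  }
  f_stat <- function(lab) {
    sw <- ss_within_for(lab)
    sb <- ss_total - sw
    if (sw <= 0) {
      if (sb > 0) Inf else 0
    } else {
      (sb / (a - 1)) / (sw / (n - a))
    }
  }
  ss_within <- ss_within_for(labels)
  ss_between <- ss_total - ss_within
  r2 <- if (ss_total > 0) ss_between / ss_total else 0
  f_obs <- f_stat(labels)
  exceed <- with_local_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      f_stat(sample(labels)) >= f_obs
    }, logical(1)))
  })
  structure(
    list(r_squared = r2, pseudo_f = f_obs,
         p_value = (1 + exceed) / (1 + n_perm),
         n_permutations = n_perm, seed = seed,
         ss = c(total = ss_total, within = ss_within, between = ss_between)),
    class = "permanova_result"
  )
}

#' @exportS3Method base::print
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F = %.3f, p = %.4g (%d perms)\n",
              x$r_squared, x$pseudo_f, x$p_value, x$n_permutations))
  invisible(x)
}

#' Individual fingerprint classification from a distance matrix
#'
#' Tests whether post-treatment samples can still be matched to their
#' subject: each post sample is assigned to the subject whose baseline
#' (day-0) sample is nearest under the metric. Low accuracy indicates the
#' intervention overwrote the individual-specific compositional fingerprint.
#' With `reference = "all"` the candidate set is instead every other sample
#' (leave-self-out) and a hit is any sample of the true subject.
#'
#' @param dm A `distance_matrix` containing all design samples.
#' @param design A `paired_design`.
#' @param reference `"baseline"` (default) or `"all"`.
#' @return A `fingerprint_result` list: `accuracy`, `assignments` (per post
#'   sample: true and assigned subject, rank of the true baseline, tie flag,
#'   arm), `per_arm` accuracy table, `degenerate` flag (single subject).
#' @export
fingerprint_assignment <- function(dm, design,
                                   reference = c("baseline", "all")) {
  reference <- match.arg(reference)
  stopifnot(inherits(design, "paired_design"))
  d <- as.matrix(dm)
  need <- c(design$pre_sample_id, design$post_sample_id)
  missing_s <- setdiff(need, colnames(d))
  if (length(missing_s)) {
    stop("distance matrix lacks sample(s): ",
         paste(head(missing_s, 5), collapse = ", "), call. = FALSE)
  }
  subj_of <- c(setNames(design$subject_id, design$pre_sample_id),
               setNames(design$subject_id, design$post_sample_id))
  rows <- lapply(seq_len(nrow(design)), function(i) {
    post_s <- design$post_sample_id[i]
    true_subj <- design$subject_id[i]
    if (reference == "baseline") {
      cand <- design$pre_sample_id
    } else {
      cand <- setdiff(need, post_s)
    }
    dd <- d[post_s, cand]
    # deterministic tie-break: nearest distance, then lexicographic subject
    ord <- order(dd, subj_of[cand], method = "radix")
    nearest <- cand[ord[1]]
    tie <- sum(dd == dd[ord[1]]) > 1L
    assigned <- unname(subj_of[nearest])
    true_hits <- which(subj_of[cand][ord] == true_subj)
    data.frame(
      post_sample_id = post_s, true_subject = true_subj,
      assigned_subject = assigned, correct = assigned == true_subj,
      rank_true = true_hits[1], tie = tie, arm = design$arm[i],
      stringsAsFactors = FALSE
    )
  })
  assignments <- do.call(rbind, rows)
  acc <- mean(assignments$correct)
  per_arm <- stats::aggregate(correct ~ arm, data = assignments, FUN = mean)
  colnames(per_arm) <- c("arm", "accuracy")
  structure(
    list(accuracy = acc, assignments = assignments, per_arm = per_arm,
         reference = reference, metric = attr(dm, "metric") %||% NA_character_,
         degenerate = length(unique(design$subject_id)) < 2L),
    class = "fingerprint_result"
  )
}

#' @exportS3Method base::print
print.fingerprint_result <- function(x, ...) {
  cat(sprintf("Fingerprint assignment (%s, reference = %s): accuracy %.3f over %d post samples%s\n",
              x$metric, x$reference, x$accuracy, nrow(x$assignments),
              if (x$degenerate) " [degenerate: single subject]" else ""))
  invisible(x)
}

#' Fingerprint accuracy across several dissimilarity metrics
#'
#' Convenience wrapper computing [fingerprint_assignment()] per metric and
#' per arm — the machine-readable analogue of an accuracy heatmap.
#'
#' @param tab Species `abundance_table` containing all design samples.
#' @param design A `paired_design`.
#' @param metrics Metrics to evaluate (see [distance_matrix()]).
#' @return Data frame with columns `metric`, `arm`, `accuracy`, `n_post`.
#' @export
fingerprint_accuracy <- function(tab, design,
                                 metrics = c("bray_curtis", "hellinger",
                                             "spearman", "jsd")) {
  rows <- lapply(metrics, function(m) {
    dm <- distance_matrix(tab, m)
    fr <- fingerprint_assignment(dm, design)
    n_post <- table(fr$assignments$arm)
    data.frame(metric = m, arm = fr$per_arm$arm,
               accuracy = fr$per_arm$accuracy,
               n_post = as.integer(n_post[fr$per_arm$arm]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
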
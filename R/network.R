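#' Build a species co-occurrence network
#'
#' For one group of samples (e.g. one arm at one timepoint): features are
#' filtered to prevalence >= `min_prevalence` (fraction of samples with
#' positive abundance), pairwise Spearman correlations are computed on CLR
#' values, and a signed edge is drawn when `|rho| >= rho_threshold` and the
#' BH-adjusted correlation p (t approximation across all pairs in the call)
#' is below `alpha`.
#'
#' @param tab Species `abundance_table`.
#' @param sample_subset Character vector of sample ids (>= 10).
#' @param min_prevalence Minimum prevalence to keep a feature.
#' @param rho_threshold Absolute correlation threshold for edges.
#' @param alpha BH-adjusted p threshold for edges.
#' @param pseudocount CLR pseudocount policy.
#' @return A `cooccurrence_network`: list with `graph` (igraph, undirected,
#'   edge attributes `rho`, `p_bh`, `sign`), `edges` (data frame `feature_a`,
#'   `feature_b`, `rho`, `p_raw`, `p_bh`, `sign`), `nodes`, `n_samples`.
#' @export
build_network <- function(tab, sample_subset, min_prevalence = 0.2,
                          rho_threshold = 0.3, alpha = 0.05,
                          pseudocount = "half-min") {
  stopifnot(inherits(tab, "abundance_table"))
  sample_subset <- as.character(sample_subset)
  missing_s <- setdiff(sample_subset, colnames(tab$values))
  if (length(missing_s)) {
    stop("table lacks sample(s): ", paste(head(missing_s, 5), collapse = ", "),
         call. = FALSE)
  }
  if (length(sample_subset) < 10L) {
    stop("need >= 10 samples to infer a co-occurrence network", call. = FALSE)
  }
  sub <- tab$values[, sample_subset, drop = FALSE]
  prev <- rowMeans(sub > 0)
  keep <- names(prev)[prev >= min_prevalence]
  if (length(keep) < 2L) {
    stop("fewer than 2 features pass the prevalence filter", call. = FALSE)
  }
  subtab <- abundance_table(sub[keep, , drop = FALSE], tab$kind)
  clr <- clr_transform(to_relative(subtab), pseudocount = pseudocount)
  n <- ncol(clr)
  ranks <- t(apply(clr, 1, rank))
  rho <- suppressWarnings(cor(t(ranks)))
  # t-approximation p for Spearman rho (mid-ranks)
  pr <- which(upper.tri(rho), arr.ind = TRUE)
  rr <- rho[pr]
  rr_c <- pmin(pmax(rr, -1 + 1e-15), 1 - 1e-15)
  tstat <- rr_c * sqrt((n - 2) / (1 - rr_c^2))
  p_raw <- 2 * pt(-abs(tstat), df = n - 2)
  p_raw[is.na(rr)] <- 1
  rr[is.na(rr)] <- 0
  p_bh <- bh_adjust(p_raw)
  sel <- abs(rr) >= rho_threshold & p_bh < alpha
  edges <- data.frame(
    feature_a = keep[pr[sel, 1]], feature_b = keep[pr[sel, 2]],
    rho = rr[sel], p_raw = p_raw[sel], p_bh = p_bh[sel],
    sign = ifelse(rr[sel] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$feature_a, edges$feature_b), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("feature_a", "feature_b")], directed = FALSE,
    vertices = data.frame(name = keep, stringsAsFactors = FALSE)
  )
  if (nrow(edges)) {
    igraph::E(g)$rho <- edges$rho
    igraph::E(g)$p_bh <- edges$p_bh
    igraph::E(g)$sign <- edges$sign
  }
  structure(
    list(graph = g, edges = edges, nodes = keep,
         n_samples = length(sample_subset),
         params = list(min_prevalence = min_prevalence,
                       rho_threshold = rho_threshold, alpha = alpha)),
    class = "cooccurrence_network"
  )
}

#' Summary properties of a co-occurrence network
#'
#' Density `2E / (N(N-1))`, connectivity (mean node degree `2E/N`), global
#' clustering coefficient (transitivity: 3 triangles / connected triples),
#' modularity of the greedy modularity-maximizing partition on the unsigned
#' skeleton, and the fraction of positive-sign edges. An edgeless graph
#' yields zeros with `degenerate = TRUE`.
#'
#' @param net A `cooccurrence_network` or an igraph graph.
#' @return A `network_summary` one-row data frame: `n_nodes`, `n_edges`,
#'   `density`, `connectivity`, `clustering_coefficient`, `modularity`,
#'   `positive_edge_fraction`, `degenerate`.
#' @export
network_properties <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  stopifnot(igraph::is_igraph(g))
  n_nodes <- igraph::vcount(g)
  if (n_nodes < 1L) stop("graph has no nodes", call. = FALSE)
  n_edges <- igraph::ecount(g)
  degenerate <- n_edges == 0L
  density <- if (n_nodes > 1L) 2 * n_edges / (n_nodes * (n_nodes - 1)) else 0
  connectivity <- 2 * n_edges / n_nodes
  clustering <- if (degenerate) 0 else {
    tr <- igraph::transitivity(g, type = "global")
    if (is.nan(tr)) 0 else tr
  }
  modularity <- if (degenerate) 0 else {
    comm <- igraph::cluster_fast_greedy(
      igraph::simplify(g, edge.attr.comb = "first"))
    igraph::modularity(comm)
  }
  pos_frac <- if (degenerate) 0 else {
    sg <- igraph::edge_attr(g, "sign")
    if (is.null(sg)) 1 else mean(sg == "positive")
  }
  out <- data.frame(
    n_nodes = n_nodes, n_edges = n_edges, density = density,
    connectivity = connectivity, clustering_coefficient = clustering,
    modularity = modularity, positive_edge_fraction = pos_frac,
    degenerate = degenerate, stringsAsFactors = FALSE
  )
  class(out) <- c("network_summary", "data.frame")
  out
}

#' Differential network analysis between pre and post timepoints
#'
#' Builds the arm's co-occurrence network at baseline and at `post_day`,
#' takes the observed post-minus-pre delta of each requested property, and
#' assesses it against a null in which each subject's pre/post labels are
#' swapped independently with probability 1/2 and both networks rebuilt
#' (two-sided `p = (1 + #{|permuted delta| >= |observed|}) / (1 + n_perm)`).
#'
#' @param tab Species `abundance_table`.
#' @param meta A `cohort_metadata`.
#' @param arm Arm to analyze.
#' @param post_day Post-treatment day.
#' @param properties Character vector of `network_summary` columns to test.
#' @param n_perm Number of within-subject label permutations (a warning is
#'   issued below 99).
#' @param seed RNG seed.
#' @param ... Passed to [build_network()].
#' @return Data frame of class `differential_network_result`: `property`,
#'   `pre_value`, `post_value`, `observed_delta`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
differential_network <- function(tab, meta, arm, post_day,
                                 properties = c("n_edges", "density",
                                                "connectivity",
                                                "clustering_coefficient",
                                                "modularity"),
                                 n_perm = 199, seed = 1, ...) {
  stopifnot(inherits(tab, "abundance_table"), inherits(meta, "cohort_metadata"))
  if (n_perm < 99) warning("n_perm < 99 gives a coarse permutation p value")
  design <- build_paired_design(meta, post_day)
  design <- design[design$arm == arm, , drop = FALSE]
  if (nrow(design) < 10L) {
    stop("need >= 10 paired subjects in the arm", call. = FALSE)
  }
  props_for <- function(pre_ids, post_ids) {
    pre_net <- build_network(tab, pre_ids, ...)
    post_net <- build_network(tab, post_ids, ...)
    list(pre = network_properties(pre_net), post = network_properties(post_net))
  }
  obs <- props_for(design$pre_sample_id, design$post_sample_id)
  bad <- setdiff(properties, colnames(obs$pre))
  if (length(bad)) {
    stop("unknown network propert(ies): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  obs_delta <- vapply(properties, function(p) {
    obs$post[[p]] - obs$pre[[p]]
  }, numeric(1))
  n_sub <- nrow(design)
  exceed <- setNames(numeric(length(properties)), properties)
  with_local_seed(seed, {
    for (b in seq_len(n_perm)) {
      swap <- runif(n_sub) < 0.5
      pre_ids <- ifelse(swap, design$post_sample_id, design$pre_sample_id)
      post_ids <- ifelse(swap, design$pre_sample_id, design$post_sample_id)
      pm <- props_for(pre_ids, post_ids)
      for (p in properties) {
        if (abs(pm$post[[p]] - pm$pre[[p]]) >= abs(obs_delta[[p]])) {
          exceed[[p]] <- exceed[[p]] + 1
        }
      }
    }
  })
  out <- data.frame(
    property = properties,
    pre_value = vapply(properties, function(p) obs$pre[[p]], numeric(1)),
    post_value = vapply(properties, function(p) obs$post[[p]], numeric(1)),
    observed_delta = unname(obs_delta),
    p_value = unname((1 + exceed) / (1 + n_perm)),
    n_permutations = n_perm, seed = seed,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("differential_network_result", "data.frame")
  out
}
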
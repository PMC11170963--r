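#' Configuration for the synthetic paired cohort
#'
#' Builds the parameter set for [simulate_cohort()]. The generator emulates
#' a multi-arm paired (pre/post) drug-intervention microbiome study: stable
#' per-subject compositional fingerprints, arm-specific treatment effects on
#' a planted subset of species, functional genes linked to species, and
#' clinical glycemic responses partially driven by baseline microbial
#' features.
#'
#' The log-scale abundance model for species `i`, subject `s`, timepoint `t`
#' is `x_ist = mu_i + a_is + (delta_i + eta_is) * 1[t = post, arm affected]
#' + eps_ist` with `a_is ~ N(0, subject_sd^2)` (the subject fingerprint),
#' `eps ~ N(0, noise_sd^2)`, `delta_i ~ N(0, effect_sd^2)` for the affected
#' fraction of species in each arm, and `eta_is ~ N(0, (interaction_scale *
#' |delta_i|)^2)` the subject's individual deviation from the shared drug
#' response (constant across post-treatment timepoints). Compositions are obtained by
#' softmax closure per sample; structural zeros are then injected by
#' truncating the lowest `zero_quantile` fraction of each species' values
#' to 0 and re-closing.
#'
#' Default arm effects mirror the qualitative pattern of multi-drug trials:
#' two strongly perturbing arms (`acarbose`, `berberine`), three mild arms
#' (`metformin`, `vildagliptin`, `glipizide`) and a null `placebo` arm.
#' Clinical pre-treatment values and drug/placebo shifts default to values
#' typical of newly diagnosed type-2-diabetes trial reports (HbA1c about
#' 7.7% falling by about 1.3 points under active drug, 0.6 under placebo).
#'
#' @param n_subjects Total subjects, divided round-robin across arms.
#' @param n_species,n_genes Feature counts for the two tables.
#' @param arm_effects Named list: per arm a list with `affected_fraction`
#'   (share of species perturbed) and `effect_sd` (log-scale magnitude).
#' @param subject_sd,noise_sd Log-scale between-subject and within-subject
#'   standard deviations.
#' @param mu_sd Log-scale spread of species mean abundances.
#' @param zero_quantile Per-species fraction of lowest values truncated to
#'   zero (structural sparsity).
#' @param gene_link `"random(k)"` (each gene fed by k species, positive
#'   weights) or an explicit non-negative `n_species x n_genes` matrix.
#' @param gene_scale,gene_noise_sd RPKM scale factor and half-normal noise
#'   SD for gene abundances.
#' @param timepoints Integer sampling days; first must be 0 (baseline).
#' @param effect_weighting `"abundance"` (default) draws the affected
#'   species with probability proportional to their baseline mean
#'   abundance, mirroring that drug-responsive taxa are reported among the
#'   prevalent, abundant members of the community; `"uniform"` draws them
#'   uniformly.
#' @param interaction_scale Subject-by-treatment interaction: each
#'   subject's individual response to an affected species is drawn around
#'   the shared arm effect with standard deviation `interaction_scale *
#'   |effect|`. Individual response heterogeneity is what lets a strong
#'   intervention overwrite subject fingerprints; 0 disables it.
#' @param response_model Per-measure list with `selected_features` (species
#'   indices or names), `coefficients` (effect of the baseline CLR value on
#'   the post-minus-pre change), and `noise_sd`. `NULL` gives a default with
#'   three planted species per measure.
#' @param clinical_baseline Per-measure list with `mean`, `sd`, `drug_shift`,
#'   `placebo_shift` for pre values and treatment main effects.
#' @param seed Integer RNG seed; identical config implies identical cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 180,
                             n_species = 100,
                             n_genes = 30,
                             arm_effects = NULL,
                             subject_sd = 2,
                             noise_sd = 0.3,
                             mu_sd = 2,
                             zero_quantile = 0.2,
                             gene_link = "random(3)",
                             gene_scale = 100,
                             gene_noise_sd = 1,
                             timepoints = c(0L, 84L),
                             effect_weighting = c("abundance", "uniform"),
                             interaction_scale = 1,
                             response_model = NULL,
                             clinical_baseline = NULL,
                             seed = 1) {
  effect_weighting <- match.arg(effect_weighting)
  if (interaction_scale < 0) {
    stop("interaction_scale must be >= 0", call. = FALSE)
  }
  if (is.null(arm_effects)) {
    arm_effects <- list(
      acarbose     = list(affected_fraction = 0.3,  effect_sd = 1.5),
      berberine    = list(affected_fraction = 0.3,  effect_sd = 1.5),
      metformin    = list(affected_fraction = 0.05, effect_sd = 0.8),
      vildagliptin = list(affected_fraction = 0.05, effect_sd = 0.8),
      glipizide    = list(affected_fraction = 0.05, effect_sd = 0.8),
      placebo      = list(affected_fraction = 0,    effect_sd = 0)
    )
  }
  if (is.null(clinical_baseline)) {
    clinical_baseline <- list(
      hba1c   = list(mean = 7.7,  sd = 0.8, drug_shift = -1.3,
                     placebo_shift = -0.6),
      fpg     = list(mean = 9.0,  sd = 1.5, drug_shift = -1.5,
                     placebo_shift = -0.4),
      ppg     = list(mean = 13.5, sd = 2.5, drug_shift = -2.5,
                     placebo_shift = -0.6),
      homa_ir = list(mean = 4.0,  sd = 1.2, drug_shift = -0.8,
                     placebo_shift = -0.2)
    )
  }
  if (is.null(response_model)) {
    measures <- names(clinical_baseline)
    response_model <- setNames(lapply(seq_along(measures), function(k) {
      list(selected_features = ((k - 1) * 3 + 1):((k - 1) * 3 + 3),
           coefficients = c(0.4, -0.4, 0.3),
           noise_sd = 0.5)
    }), measures)
  }
  for (a in names(arm_effects)) {
    ae <- arm_effects[[a]]
    if (ae$affected_fraction < 0 || ae$affected_fraction > 1) {
      stop("affected_fraction must be in [0, 1]", call. = FALSE)
    }
    if (ae$effect_sd < 0) stop("effect_sd must be >= 0", call. = FALSE)
  }
  if (subject_sd < 0 || noise_sd < 0 || mu_sd < 0) {
    stop("sd parameters must be >= 0", call. = FALSE)
  }
  for (m in names(response_model)) {
    rm_ <- response_model[[m]]
    if (length(rm_$selected_features) != length(rm_$coefficients)) {
      stop("selected_features and coefficients must have equal length",
           call. = FALSE)
    }
  }
  if (n_subjects < 3L) stop("n_subjects must be >= 3", call. = FALSE)
  if (timepoints[1] != 0L) stop("first timepoint must be day 0", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_species = as.integer(n_species), n_genes = as.integer(n_genes),
         arm_effects = arm_effects, subject_sd = subject_sd,
         noise_sd = noise_sd, mu_sd = mu_sd, zero_quantile = zero_quantile,
         gene_link = gene_link, gene_scale = gene_scale,
         gene_noise_sd = gene_noise_sd,
         timepoints = as.integer(timepoints),
         effect_weighting = effect_weighting,
         interaction_scale = interaction_scale,
         response_model = response_model,
         clinical_baseline = clinical_baseline, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Simulate a paired pre/post intervention cohort
#'
#' Draws a full synthetic cohort under the model described in
#' [synthetic_config()]: a species relative-abundance table, a species-linked
#' gene RPKM table, per-sample metadata with clinical measures, and the
#' planted ground truth. The same config (including its seed) always yields
#' a bit-identical cohort.
#'
#' @param config A `synthetic_config`.
#' @return List with elements `species` (`abundance_table`,
#'   relative_abundance), `genes` (`abundance_table`, rpkm), `metadata`
#'   (`cohort_metadata`) and `truth` (`ground_truth`: `affected_species` per
#'   arm, `response_coefficients`, `subject_effects`, `gene_link`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    n_sub <- cfg$n_subjects
    n_sp <- cfg$n_species
    arms <- names(cfg$arm_effects)
    subj_arm <- rep(arms, length.out = n_sub)
    subject_ids <- sprintf("S%03d", seq_len(n_sub))
    sp_ids <- sprintf("sp%03d", seq_len(n_sp))
    days <- cfg$timepoints

    mu <- rnorm(n_sp, 0, cfg$mu_sd)
    subj_eff <- matrix(rnorm(n_sp * n_sub, 0, cfg$subject_sd), n_sp, n_sub,
                       dimnames = list(sp_ids, subject_ids))

    # planted per-arm treatment effects; drug-responsive species are drawn
    # weighted by baseline mean abundance (drug effects are observed on the
    # prevalent, abundant fraction of the community)
    sp_weight <- if (identical(cfg$effect_weighting, "abundance")) {
      exp(mu - max(mu))
    } else {
      rep(1, n_sp)
    }
    affected <- lapply(arms, function(a) {
      ae <- cfg$arm_effects[[a]]
      k <- round(ae$affected_fraction * n_sp)
      if (ae$affected_fraction > 0 && k < 1) {
        warning(sprintf("arm '%s': affected fraction selects < 1 species; treated as null arm", a))
        k <- 0
      }
      if (k == 0) {
        return(data.frame(species = character(0), effect = numeric(0),
                          stringsAsFactors = FALSE))
      }
      idx <- sample.int(n_sp, k, prob = sp_weight)
      eff <- rnorm(k, 0, ae$effect_sd)
      # centre the log effects within the affected set: under compositional
      # closure only the centred component of a log-fold perturbation is
      # identifiable, so an uncentred remainder would alias into every
      # unaffected species rather than being recoverable ground truth
      if (k > 1L) eff <- eff - mean(eff)
      data.frame(species = sp_ids[idx], effect = eff,
                 stringsAsFactors = FALSE)
    })
    names(affected) <- arms

    sample_ids <- as.vector(t(outer(subject_ids, days,
                                    function(s, d) sprintf("%s_D%d", s, d))))
    n_samp <- length(sample_ids)
    logx <- matrix(0, n_sp, n_samp, dimnames = list(sp_ids, sample_ids))
    col <- 0L
    for (s in seq_len(n_sub)) {
      a <- subj_arm[s]
      delta <- setNames(rep(0, n_sp), sp_ids)
      if (nrow(affected[[a]])) {
        delta[affected[[a]]$species] <- affected[[a]]$effect
      }
      # subject-by-treatment interaction: individual responses scatter
      # around the shared arm effect, proportionally to its size, so strong
      # perturbations also overwrite the subject's compositional fingerprint
      eta <- rnorm(n_sp, 0, cfg$interaction_scale * abs(delta))
      for (d in days) {
        col <- col + 1L
        treat <- if (d > 0L) delta + eta else 0
        logx[, col] <- mu + subj_eff[, s] + treat +
          rnorm(n_sp, 0, cfg$noise_sd)
      }
    }
    # softmax closure per sample
    rel <- apply(logx, 2, function(x) {
      e <- exp(x - max(x))
      e / sum(e)
    })
    dimnames(rel) <- dimnames(logx)
    # structural zeros: a global detection floor at the zero_quantile of all
    # relative abundances, so the lowest q% of entries fall below detection.
    # Zeros concentrate in each sample's rare tail (as profiler detection
    # limits do), and the smallest surviving value sits at the floor, so a
    # half-minimum pseudocount stays commensurate with the censored values
    if (cfg$zero_quantile > 0) {
      thr <- quantile(as.vector(rel), probs = cfg$zero_quantile,
                      names = FALSE)
      rel[rel <= thr] <- 0
      cs <- colSums(rel)
      if (any(cs <= 0)) stop("zero truncation emptied a sample; lower zero_quantile")
      rel <- sweep(rel, 2, cs, "/")
    }
    species <- abundance_table(rel, "relative_abundance")

    # gene abundances linked to species
    if (is.character(cfg$gene_link) &&
        grepl("^random\\((\\d+)\\)$", cfg$gene_link)) {
      k <- as.integer(sub("^random\\((\\d+)\\)$", "\\1", cfg$gene_link))
      link <- matrix(0, n_sp, cfg$n_genes)
      for (g in seq_len(cfg$n_genes)) {
        link[sample.int(n_sp, min(k, n_sp)), g] <- runif(min(k, n_sp), 0.5, 1.5)
      }
    } else {
      link <- cfg$gene_link
      if (!is.matrix(link) || any(link < 0) ||
          nrow(link) != n_sp || ncol(link) != cfg$n_genes) {
        stop("gene_link must be 'random(k)' or a non-negative n_species x n_genes matrix",
             call. = FALSE)
      }
    }
    gene_ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
    dimnames(link) <- list(sp_ids, gene_ids)
    gmat <- t(link) %*% rel * cfg$gene_scale +
      abs(matrix(rnorm(cfg$n_genes * n_samp, 0, cfg$gene_noise_sd),
                 cfg$n_genes, n_samp))
    dimnames(gmat) <- list(gene_ids, sample_ids)
    genes <- abundance_table(gmat, "rpkm")

    # clinical responses driven by baseline CLR features
    baseline_cols <- sprintf("%s_D0", subject_ids)
    clr_base <- clr_transform(
      abundance_table(rel[, baseline_cols, drop = FALSE],
                      "relative_abundance"))
    age <- round(rnorm(n_sub, 52, 8))
    sex <- ifelse(runif(n_sub) < 0.58, "male", "female")
    bmi <- round(rnorm(n_sub, 26.2, 3), 1)
    measures <- names(cfg$clinical_baseline)
    pre_vals <- post_vals <- matrix(NA_real_, n_sub, length(measures),
                                    dimnames = list(subject_ids, measures))
    resp_truth <- list()
    for (m in measures) {
      cb <- cfg$clinical_baseline[[m]]
      rm_ <- cfg$response_model[[m]]
      sel <- rm_$selected_features
      if (is.numeric(sel)) sel <- sp_ids[sel]
      pre_vals[, m] <- rnorm(n_sub, cb$mean, cb$sd)
      shift <- ifelse(subj_arm == "placebo", cb$placebo_shift, cb$drug_shift)
      micro <- as.vector(t(clr_base[sel, , drop = FALSE]) %*% rm_$coefficients)
      post_vals[, m] <- pre_vals[, m] + shift + micro +
        rnorm(n_sub, 0, rm_$noise_sd)
      resp_truth[[m]] <- data.frame(feature = sel,
                                    coefficient = rm_$coefficients,
                                    stringsAsFactors = FALSE)
    }

    md <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
      do.call(rbind, lapply(days, function(d) {
        row <- data.frame(
          sample_id = sprintf("%s_D%d", subject_ids[s], d),
          subject_id = subject_ids[s], arm = subj_arm[s],
          timepoint_day = d, age = age[s], sex = sex[s], bmi = bmi[s],
          stringsAsFactors = FALSE
        )
        for (m in measures) {
          row[[m]] <- if (d == 0L) pre_vals[s, m] else post_vals[s, m]
        }
        row
      }))
    }))
    metadata <- cohort_metadata(md)

    truth <- structure(
      list(affected_species = affected,
           response_coefficients = resp_truth,
           subject_effects = subj_eff,
           gene_link = link,
           arm_of_subject = setNames(subj_arm, subject_ids)),
      class = "ground_truth"
    )
    list(species = species, genes = genes, metadata = metadata, truth = truth)
  })
}

#' Tabulate the planted signals of a synthetic cohort
#'
#' @param truth A `ground_truth` from [simulate_cohort()].
#' @return Data frame with columns `arm`, `species`, `effect`, `direction`
#'   (one row per planted species effect; null arms contribute no rows).
#' @export
planted_signal_report <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  rows <- lapply(names(truth$affected_species), function(a) {
    df <- truth$affected_species[[a]]
    if (!nrow(df)) return(NULL)
    data.frame(arm = a, species = df$species, effect = df$effect,
               direction = ifelse(df$effect > 0, "increased", "decreased"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(arm = character(0), species = character(0),
                      effect = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}
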
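---
title: "Models and methods for paired drug-intervention microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for paired drug-intervention microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedbiome)
```

## The analysis problem

Multi-arm drug-intervention trials in type-2-diabetes patients sample each
subject's gut metagenome before treatment (day 0) and after a fixed
intervention period (one to several months), together with glycemic
measures (HbA1c, fasting and postprandial glucose, HOMA-IR). Three
questions structure the analysis:

1. **How much does each drug restructure the community?** Alpha diversity
   (richness, Shannon) tested pre vs post per arm; community-level shifts
   under four dissimilarity metrics quantified by PERMANOVA R²; and a
   distance-based *fingerprint* classification asking whether a
   post-treatment sample can still be matched to its subject's baseline.
   Strongly perturbing drugs (alpha-glucosidase inhibitors such as
   acarbose, or berberine) collapse this match; milder drugs (metformin,
   vildagliptin, glipizide) and placebo leave it intact.
2. **Which species and functional genes move?** Paired Wilcoxon
   signed-rank tests on centered log-ratio (CLR) species abundances and on
   gene RPKM, with signed-rank effect sizes and Benjamini–Hochberg
   correction; rank-sum tests compare post-treatment samples across arms.
   Species co-occurrence networks summarize community rewiring.
3. **Does the baseline microbiota predict the clinical response?**
   Partial Spearman screening, elastic-net variance explained, responder
   (median-split) logistic odds ratios, and longitudinal GEE
   associations.

Every stage is validated on a synthetic cohort generator with planted
ground truth; the generator is first-class, tested code.

## The synthetic cohort model

Log-scale abundance of species $i$ in subject $s$ at timepoint $t$:

$$x_{ist} = \mu_i + a_{is} + (\delta_i + \eta_{is})\,
  \mathbf{1}[t>0,\ \text{arm affected}] + \varepsilon_{ist}$$

* $\mu_i \sim N(0, \texttt{mu\_sd}^2)$ — species mean abundances
  (default sd 2, a realistic multi-log spread of gut species).
* $a_{is} \sim N(0, \texttt{subject\_sd}^2)$ — the subject fingerprint
  (default 2): stable individual deviations, constant across timepoints.
* $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$ — within-subject
  day-to-day variation (default 0.3, well below the fingerprint, which is
  what makes pre/post samples of one subject mutual nearest neighbours).
* $\delta_i \sim N(0, \texttt{effect\_sd}^2)$ — the shared drug effect on
  an arm-specific affected fraction of species.
* $\eta_{is} \sim N(0, (\texttt{interaction\_scale}\cdot|\delta_i|)^2)$ —
  the subject-by-treatment interaction, drawn once per subject and applied
  to every post-treatment timepoint.

Compositions are the softmax of $x$ per sample. Structural zeros are then
injected by a global detection floor at the `zero_quantile` (default 0.2)
of all relative abundances, and columns re-closed; zeros therefore
concentrate in each sample's rare tail, as profiler detection limits do,
and the smallest surviving value sits at the floor so that the half-minimum
CLR pseudocount stays commensurate with the censored values. An earlier
design that truncated each species' own lowest values instead produced
zeros at high abundances, which put the pseudocount several logs below the
censored values and visibly distorted the CLR geometric mean.

Three generator choices deserve explicit justification:

* **Affected species are drawn weighted by baseline abundance**
  (`effect_weighting = "abundance"`). Drug-responsive taxa are reported
  among the prevalent, abundant community members; uniform sampling
  instead concentrates effects on rare species that carry no mass under
  Bray–Curtis.
* **Individual response heterogeneity is required for fingerprint
  destruction.** A treatment shift shared identically by all subjects can
  never erase between-subject differences: for any approximately additive
  metric, the within-pair displacement $\sqrt{0.3\,n\,\sigma_\delta^2}$
  stays far below the cross-subject spread
  $\sqrt{2\,n\,\sigma_{\text{subject}}^2}$ at the magnitudes of interest.
  The interaction term $\eta_{is}$ is what lets a strong arm overwrite
  fingerprints, reproducing the qualitative accuracy pattern of strong vs
  mild drugs, while leaving null arms untouched ($\delta = 0 \Rightarrow
  \eta = 0$).
* **Planted log effects are centred within the affected set.** Under
  compositional closure only the centred component of a log-fold
  perturbation is identifiable; an uncentred remainder is aliased into
  every unaffected species and would make the planted "truth"
  unrecoverable by any correct method.

Default arm structure: two strong arms (`acarbose`, `berberine`: 30% of
species, effect sd 1.5), three mild arms (`metformin`, `vildagliptin`,
`glipizide`: 5%, sd 0.8) and a null `placebo`. The default cohort has 180
subjects (30 per arm, within the 16–96 per-arm range of published trials),
100 species, 30 genes, sampling days 0 and 84.

Gene RPKM values are non-negative linear combinations of species
abundances (`random(3)` sparsity: three contributing species per gene)
times a scale of 100, plus half-normal noise — so gene-level tests face
species-linked signals. Clinical post values are `pre + arm shift +
beta * CLR(baseline selected species) + noise`, with pre-treatment means
and drug/placebo shifts defaulting to values typical of newly diagnosed
type-2-diabetes trial reports (HbA1c 7.7% falling by 1.3 under active
drug, 0.6 under placebo). Percentage change is `(post - pre)/pre * 100`.

## Statistical conventions

* **CLR transform**: $y_i = \ln(p_i + c) - \frac1k\sum_j \ln(p_j + c)$,
  with the pseudocount policy `"half-min"` — half the smallest non-zero
  relative abundance of the whole table, one constant table-wide so CLR
  values stay comparable across samples.
* **Wilcoxon tests**: zeros dropped, mid-ranks for ties. Signed-rank p is
  exact for $n \le 25$ tie-free (null signed-rank distribution) and for
  $n \le 12$ under ties (full $2^n$ sign-assignment enumeration);
  otherwise the normal approximation with continuity and tie correction.
  The effect size is always $r = Z/\sqrt{n}$ from the normal
  approximation ($Z/\sqrt{n_1+n_2}$ for the rank-sum), the standard
  rank-biserial-equivalent convention.
* **BH adjustment** is the step-up rule applied within one table and one
  comparison (species and genes are separate families, as they are
  reported in separate panels).
* **PERMANOVA**: $SS_{total} = \sum_{i<j} d_{ij}^2/n$, within-group
  analogues divided by group size, $R^2 = SS_B/SS_T$, pseudo-F on
  $(a-1, n-a)$ degrees of freedom; p by free relabeling with
  $p = (1 + \#\{F^\pi \ge F\})/(1 + n_{perm})$. Permutations are not
  restricted within subject; the restricted variant would test a subtly
  different null and is not what the R² decomposition conditions on.
* **Spearman dissimilarity** is scaled to $[0,1]$ as $(1-\rho)/2$ — this
  changes absolute values relative to $1-\rho$ but no ranking of pairs.
  JSD is reported as the divergence in nats (bounded by $\ln 2$), not its
  square root.
* **Fingerprint assignment** is top-1 nearest *baseline* (day-0 samples
  only); ties break lexicographically by subject identifier and are
  flagged. A leave-self-out variant over all samples is available via
  `reference = "all"`.
* **Networks**: Spearman correlation on CLR values of features with
  prevalence ≥ 0.2, edges at $|\rho| \ge 0.3$ and BH-adjusted correlation
  p < 0.05 (all config-exposed; no published construction details exist
  to follow). Connectivity is mean degree; clustering is global
  transitivity; modularity is the greedy maximization on the unsigned
  skeleton (deterministic); signed edges are kept for the positive-edge
  fraction. Differential network p values permute timepoint labels within
  subject (pre/post swapped with probability ½), rebuilding both networks
  each time.
* **Response layer**: partial Spearman rank-transforms feature, response
  *and* covariates before residualizing (residualizing ranks on raw
  covariates leaves monotone confounding behind); significance requires
  both $|\rho| > 0.3$ and p < 0.05, strictly. The elastic net uses mixing
  0.5, 5-fold CV at a fixed seed, and selects at `lambda.1se`; the
  CV-minimum penalty selects substantially more features and inflates the
  stage-2 in-sample R² (≈0.49 for a true 0.4 at n = 200, p = 50), while
  the sparser rule tracks the truth. Both the in-sample refit R² and the
  cross-validated R² are reported side by side: at small per-arm n the
  in-sample value overfits and the CV value is the honest summary. High
  responders are strictly below the median percentage change; exact-median
  ties go to low responders for determinism. Odds ratios are per SD for
  continuous features (binary features stay on their own scale so the 2×2
  collapse equals the cross-product ratio); complete separation is
  flagged with `NA` estimates rather than reported as huge numbers. The
  GEE is Gaussian, identity link, exchangeable working correlation, with
  robust sandwich errors, implemented in-package and equal to OLS in the
  independent-cluster limit.

## What the tests do and do not show

The validation suite covers: formula-level agreement of all four
dissimilarities with brute-force oracles; exact rank-test p values against
full enumeration; BH against its definition; PERMANOVA against exact
relabeling enumeration and an independent sum-of-squares decomposition;
graph properties against an adjacency-matrix oracle; fingerprint
persistence/destruction/monotonicity; differential-abundance type-I
calibration (pooled rate 0.03–0.07 on null cohorts) and planted-signal
recovery (sensitivity ≥ 0.8, no sign errors); elastic-net recovery of
planted predictors with calibrated R²; covariate-mediation nulls; OR
coverage; and byte-identical CLI reruns. Typical problem sizes are 40–50
subjects, 50–100 species, 10–20 replicate seeds — chosen so that each
property is measured with adequate replication while the whole suite runs
in about a minute.

Passing these tests shows the *methods* are correct and calibrated under
the generator's assumptions. The generator emulates paired compositional
fingerprints, arm-specific effects, species-linked genes and
microbiota-dependent responses; it does not emulate sequencing counts
(abundances are continuous), strain-level variation, covariate-correlated
effects (age/sex/BMI are independent of the microbiome), longitudinal
drift beyond two timepoints, or batch effects. Results on real data
additionally depend on profiling pipelines and cohort structure that no
synthetic test certifies.

One property fails by design rather than by defect: under censored
compositions, flagged species cannot match the planted set perfectly.
Strong planted effects push competitors' relative abundances across the
detection floor, so a few non-planted — mostly rare, frequently censored —
species are *correctly* flagged as changed in relative abundance. The
suite therefore asserts sensitivity, sign correctness and the rarity
profile of the extra discoveries, not exact set recovery.

## Known limitations

* CLR with a pseudocount is sensitive to the censoring process; the
  geometric mean couples species within a sample, so per-cohort test
  statistics are weakly positively correlated across features.
* The in-sample elastic-net R² is only meaningful when subjects comfortably
  outnumber selected features; use the CV R² otherwise.
* PERMANOVA with free permutation ignores the pairing; with strong
  subject effects this is conservative for the pre/post contrast.
* The GEE implementation supports the exchangeable structure only, which
  is adequate for the two-to-four timepoints of this design.
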
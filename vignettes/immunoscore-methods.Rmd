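---
title: "Methods: immune-infiltration typing and the prognostic immune score"
author: "immunoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-infiltration typing and the prognostic immune score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`immunoscore` implements a complete immune-heterogeneity analysis for bulk
tumour transcriptomes, developed around the prostate-cancer setting in
which it is most often applied:

1. **Infiltration scoring.** The abundance of 28 immune-cell compartments
   is estimated per sample by single-sample gene set enrichment (ssGSEA)
   of published signature gene sets.
2. **Immune typing.** Samples are clustered by consensus non-negative
   matrix factorization (NMF) of the infiltration matrix.  Progression-free
   survival (PFS) informs the choice of rank; with two clusters, the
   immune-hot cluster is named **A** and the immune-cold cluster **B**.
   In this setting cluster B carries the worse prognosis.
3. **Module discovery.** A weighted co-expression network (soft-thresholded
   unsigned adjacency, topological overlap) yields gene modules whose
   eigengenes are correlated with clusterB membership; per-gene module
   membership (MM) and gene significance (GS) follow.
4. **Hub genes and the immune score.** Genes in trait-associated modules
   with MM > 0.8 and GS > 0.5 are hubs.  The immune score of a sample is

   IS = &Sigma; PC1(B+) &minus; &Sigma; PC1(B&minus;),

   the sum over modules positively correlated with clusterB of their
   hub-gene first principal component, minus the sum over negatively
   correlated modules.  Samples are split at the survival-optimal
   cutpoint into high/low IS groups, which are then carried into
   Kaplan–Meier, fixed-horizon ROC, and covariate-stratified analyses.

Every stage is driven by `run_config()` and reproducible from
`(inputs, config)` alone.

# The ssGSEA score

Within each sample, genes are ranked (rank 1 = lowest, average ties).  For
a set $S$ with weights $r^\alpha$ the walk down the ranked list accumulates

$$ES = \sum_{\text{positions } i} \left(P^{in}(i) - P^{out}(i)\right),$$

where $P^{in}$ steps by $r_g^\alpha / \sum_{g' \in S} r_{g'}^\alpha$ at
in-set genes and $P^{out}$ by $1/(N - |S|)$ elsewhere.  We use
$\alpha = 0.25$, the conventional weighting, and optionally divide the
score matrix by its global range — an order-preserving rescaling.  Scores
are used only as abundances; no permutation p-values are attached.  The
implementation is checked against an independently coded two-ECDF brute
force to $10^{-9}$ on hundreds of random instances.

Because the score depends only on within-sample ranks, it is invariant to
any monotone per-sample normalization — and, importantly, it measures a
signature's standing **relative to the rest of the transcriptome**.  A
signature shift shared by nearly all genes would be invisible; the
synthetic generator therefore keeps signature genes a minority of the
simulated transcriptome, as they are in real data.

# Consensus NMF typing and survival-informed rank selection

The infiltration matrix is made non-negative by row-wise min–max scaling
(scores are interval-scale, so the shift is harmless and every sample
ordering is preserved) and factorized as $X \approx WH$ by multiplicative
updates for the Frobenius objective, which guarantee a non-increasing
loss (asserted on every run; defaults: 2000 iterations cap, relative
tolerance $10^{-6}$).

**Reading labels off the factorization.** The pair $(W, H)$ is only
determined up to an invertible transform $(WA^{-1}, AH)$.  The habitual
"argmax of the H column" read-out is not invariant to that ambiguity, and
it fails structurally when one cluster's profile dominates the other's on
every row — exactly the immune-hot vs immune-cold situation, where the
cold profile is a scaled-down version of the hot one rather than a
different "part".  We therefore whiten the columns of $H$ (making the
coordinates unique up to rotation, which k-means ignores) and partition
them with seeded k-means.  Eigendirections carrying less than $10^{-6}$
of the leading variance are numerical jitter of the converged
factorization and are excluded before whitening.

**Consensus and stability.** Fifty random restarts (default) vote into a
consensus matrix; final labels cut the average-linkage tree of
$1 - \text{consensus}$.  Stability per rank is summarized by the
cophenetic coefficient and by the proportion of ambiguous clustering
(PAC: the fraction of consensus entries strictly between 0.1 and 0.9).
A rank is eligible when cophenetic $\ge 0.95$ **and** PAC $\le 0.1$; the
PAC screen matters because a high-quality read-out makes even wrong ranks
fairly reproducible by the cophenetic measure alone.

**Where survival enters.** PFS affects only model selection: among
eligible ranks the one with the most significant k-group log-rank
separation (smallest p — comparable across ranks with different degrees
of freedom, unlike the raw chi-square) is chosen, ties to the smaller
rank.  The factorization itself stays fully unsupervised, the most
conservative reading of "clustering on abundance and PFS information";
nothing about the survival data can reshape the clusters themselves.

With $k = 2$ the cluster with the higher grand-mean infiltration is named
A (exact ties broken toward the cluster holding the lexicographically
smallest sample id, with a warning).  Cell-type abundances and checkpoint
genes (CTLA-4, PD-L1/CD274) are contrasted between clusters by two-sided
Wilcoxon rank-sum tests.

# Co-expression modules

The `n_top` most variable genes (median absolute deviation; default 5000,
i.e. all genes at desk scale) enter an unsigned weighted network
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$.  The power $\beta$ is the
smallest one whose connectivity distribution fits a scale-free law at
$R^2 \ge 0.85$ over ~10 log-spaced frequency bins.  Block-modular data —
including the synthetic cohorts — are *not* scale-free: every fit is poor
and the criterion carries no information about the right power.  In that
case the picker falls back to the conventional unsigned default
$\beta = 6$ (clamped to the grid) with a warning, rather than trusting
the argmax of a meaningless fit.

Adjacency is denoised into the topological overlap matrix
$\mathrm{TOM}_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$
(checked against a triple-loop oracle to $10^{-12}$), and modules come
from average-linkage clustering of $1 - \mathrm{TOM}$ with a fixed-height
cut.  The default cut height is automatic: the midpoint of the largest
gap between consecutive merge heights in the upper half of the dendrogram,
a deterministic rule that lands between the tight within-module merges
and the late between-module ones.  A fixed quantile of merge heights was
considered and rejected: the right cut fraction depends on the share of
unassigned genes, which varies across data sets, whereas the gap rule
adapts.  Clusters smaller than `min_size` (default 30) become `grey`;
surviving modules take the conventional colour names by decreasing size.
Optional eigengene-based merging (correlation $\ge 0.75$) is off by
default.

Module eigengenes are the unit-variance first principal component of the
module's z-scored expression, oriented to correlate positively with the
module's mean profile (PCA signs are otherwise arbitrary).  Module–trait
correlation, MM and GS are plain Pearson correlations against the 0/1
clusterB indicator (for more than two clusters the pipeline substitutes
the lowest-infiltration cluster).

# Hub genes and the immune score

Modules with $|r| \ge 0.5$ and $p \le 0.05$ against clusterB are selected
and tagged B+ / B&minus; by the sign of $r$; within them, genes with
MM > 0.8 and GS > 0.5 (strict inequalities) are hubs.  Degree and exact
maximal-clique-centrality (MCC) rankers are provided for user-supplied
interaction networks; MCC sums $(|C|-1)!$ over the maximal cliques
containing a node and equals the degree when all its cliques are single
edges.

The immune score interprets "&Sigma; PC1" as *per-module* PC1 scores
summed within each sign (the summation ranges over modules; with one
module per sign this coincides with a pooled PCA, which remains available
via `pooled_pc1 = TRUE`).  PC1 is computed on z-scored hub-gene
expression, keeps its raw scale (variance = leading eigenvalue), and is
sign-oriented as above — without the orientation rule the IS would not be
reproducible.  Swapping the B+/B&minus; tags negates the IS exactly.

The cutpoint is the maximally selected log-rank statistic over observed
IS values inside the 10–90% quantile window; ties prefer the more
balanced split, then the lower value.  The p-value at the selected
cutpoint is selection-inflated and reported as descriptive only — the
honest inferential statement is the separation observed on an
*independent* cohort scored the same way.

# Survival statistics

Kaplan–Meier estimation and the k-group log-rank test are delegated to
the `survival` package behind thin wrappers that enforce this package's
contracts.  The fixed-horizon ROC (default 60 months) binarizes
progression at the horizon and **excludes** subjects censored earlier,
always reporting the excluded count; inverse-probability-of-censoring
weighting is a deliberate non-goal.  AUC uses the rank formula with
average-tie handling and is verified against pair enumeration.  The 2×2
chi-square is Pearson's without continuity correction by default (Yates
by flag).  Stratified analyses cross the IS group with one covariate —
hormone therapy, radiation therapy, nodal status, or Gleason dichotomized
at ≤7 vs >7 — optionally restricted to T-stage subsets, and compare all
strata with a multi-group log-rank test.

# The synthetic-cohort generator

The generator plants exactly the structure the analysis assumes, so that
every stage can be tested against known truth:

- Two latent groups (A fraction 0.39, mirroring the reported cluster
  proportions); per-cell-type latent infiltration
  $f(c,s) = \mu_c + \delta \cdot I[\text{A}] + \varepsilon$ with
  $\delta = 3$ and $\varepsilon \sim N(0, 1.5^2)$.  The noise scale is
  chosen so that pairwise cell-type correlations land near 0.5 — positive
  and moderate, as real infiltration scores are.  A much smaller noise
  would push those correlations toward 0.9 and collapse all signatures
  into a single co-expression block, which no module detector could (or
  should) separate.
- 28 disjoint signatures of 30 genes each
  ($x = b_g + \beta_{sig} f(c,s) + N(0, 0.5^2)$, $\beta_{sig} = 2$),
  2000 unstructured background genes, and two checkpoint genes (CTLA4,
  CD274) loading on mean infiltration.  Background genes keep the
  signature genes a minority of the transcriptome, which the rank-based
  ssGSEA score requires (see above).  Disjoint signatures make module
  recovery ground truth unambiguous; real signatures overlap.
- Exponential PFS with baseline hazard 0.02/month, log hazard ratio 1
  for group B, uniform censoring on (0, 120] months; Gleason > 7 and N+
  enriched in group B; independent therapy flags; an optional
  `hormone_benefit` log-hazard shift for treated group-A samples plants
  the treatment-sensitivity interaction.
- Gaussian log2-scale expression rather than counts: the pipeline
  consumes log-transformed normalized values, so simulating at that level
  is faithful and simpler.

What passing tests on these cohorts show — and what they do not: the
pipeline provably recovers planted groups, modules, and prognostic
structure under clean Gaussian noise, disjoint signatures, and
exponential hazards.  Real cohorts add signature overlap, batch effects,
non-proportional hazards and annotation mismatch, none of which are
simulated; results on real data depend on those, not only on the
machinery verified here.

# Problem sizes and determinism

The standing benchmark used by the test-suite is one 400-sample cohort
(28 signatures × 30 genes + 2000 background genes), with co-expression on
the 1000 most variable genes, NMF ranks 2–6 × 50 restarts; a second,
independently seeded cohort plays the validation role.  Smaller cohorts
(n = 120) back the unit tests.  All randomness flows from a single
configuration seed through per-stage child seeds, and the whole pipeline
is bit-identical under a fixed seed — asserted by test.

# Known limitations

- KL-divergence NMF, sparse/graph-regularized variants and consensus
  k-means are out of scope; so are signed networks, dynamic-hybrid tree
  cutting and block-wise decomposition for very large gene sets.
- The ssGSEA variant here is the rank-walk form, not the Gaussian-kernel
  density variant.
- The cutpoint p-value is selection-inflated by construction; use the
  validation-cohort separation for inference.
- Input identifiers are assumed to share one gene-id space; no
  probe-to-gene annotation or batch correction is attempted.
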
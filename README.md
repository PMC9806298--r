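# immunoscore

Intratumoral immune heterogeneity from bulk transcriptomes: infiltration
typing and a prognostic immune score.

Tumours differ sharply in how much — and which — immune infiltrate they
carry, and in prostate cancer that heterogeneity tracks progression-free
survival (PFS) and plausibly the benefit of therapy.  `immunoscore` is an
R implementation of the full analysis chain that turns a log2 expression
matrix, a set of immune-cell signatures and a clinical table into:

1. a per-sample abundance matrix for 28 immune-cell compartments, by
   single-sample gene set enrichment (**ssGSEA**): genes are ranked within
   each sample and a set *S* scores
   `ES = Σ_i (P_in(i) − P_out(i))`, where the in-set walk steps by
   `rank^α / Σ_S rank^α` and the out-set walk by `1/(N − |S|)`;
2. an immune typing of the samples by consensus **non-negative matrix
   factorization** (`X ≈ WH`, multiplicative updates, Frobenius loss),
   with the rank chosen among stability-eligible candidates (cophenetic
   coefficient ≥ 0.95, proportion of ambiguous clustering ≤ 0.1) by the
   strongest PFS log-rank separation — clusterA = immune-hot,
   clusterB = immune-cold and poorer-prognosis;
3. co-expression **modules** from a weighted network
   (`a_ij = |cor|^β`, topological overlap, average-linkage tree cut),
   module eigengenes, module–trait correlation against clusterB, and
   per-gene module membership (MM) and gene significance (GS);
4. **hub genes** (MM > 0.8 and GS > 0.5 inside trait-associated modules,
   |r| ≥ 0.5 & p ≤ 0.05), plus degree / maximal-clique-centrality rankers
   for a user-supplied interaction network;
5. the **immune score** `IS = Σ PC1(B+) − Σ PC1(B−)` over hub-gene
   first principal components of modules positively / negatively
   correlated with clusterB, dichotomized at the maximally selected
   log-rank cutpoint, with Kaplan–Meier, 5-year-PFS ROC and
   covariate-stratified survival downstream.

A first-class synthetic-cohort generator plants the exact structure the
analysis assumes — two latent infiltration groups, signature-driven
co-expression modules, checkpoint genes tracking infiltration, and
group-dependent PFS with censoring — so the whole pipeline is testable
end-to-end with known ground truth and no external downloads.  See
`vignettes/immunoscore-methods.Rmd` for the model, parameter and design
discussion.

## Worked example

```r
library(immunoscore)

params <- simulation_params(n_samples = 200, seed = 42)
cohort <- generate_cohort(params)

cfg <- run_config(k_range = 2:4, n_restarts = 20, n_top = 1000, seed = 42)
result <- run_pipeline(cohort$expr, cohort$gene_sets, cohort$clinical, cfg)
print(result)
```

```
immunoscore pipeline result
  samples: 200   cell types scored: 28
  chosen NMF rank: 2 (cophenetic 1.000)
  cluster sizes: A=78, B=122
  cluster PFS log-rank: chisq 26.86, p 2.19e-07
  co-expression modules: 28 (beta = 6)
  hub genes: 840 in 28 module(s)
  IS cutpoint: 34; high/low log-rank p 1.05e-07; 60-month AUC 0.608
```

Reading the output: the consensus NMF picked two perfectly stable
clusters; the immune-hot clusterA (78 samples) progresses later than
clusterB (log-rank p = 2.2e-07).  The network recovered the 28 planted
signature modules at the fallback power β = 6 (block-modular data are not
scale-free, so the fit-based picker warns and falls back), all 840
signature genes pass the MM/GS hub screen, and the immune score built
from them separates PFS at its optimal cutpoint (p = 1.0e-07) with a
60-month AUC of 0.61.  Per-sample scores live in `result$is_table`;
because every planted module is *negatively* correlated with clusterB
(immune-cold samples express signature genes less), the B+ side is empty
here — the pipeline warns and the IS reduces to `−Σ PC1(B−)`, so high IS
means cold and poor-prognosis, as intended.

Individual stages are exported too (`ssgsea_matrix()`,
`consensus_cluster()`, `tom_similarity()`, `screen_hub_genes()`,
`compute_immune_score()`, `stratified_survival()`, ...), as are readers
for expression TSV, GMT, clinical TSV and edge-list files.

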
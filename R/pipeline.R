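# End-to-end driver: ssGSEA infiltration -> consensus-NMF typing ->
# co-expression modules -> hub genes -> immune score -> survival outputs.

#' Run the complete immune-typing and immune-score pipeline
#'
#' Executes every stage in order on one cohort: scores the 28 immune-cell
#' signatures per sample (ssGSEA), clusters samples by survival-informed
#' consensus NMF and names the clusters A (immune-hot) / B, builds the
#' weighted co-expression network on the most variable genes and correlates
#' module eigengenes with clusterB membership, screens hub genes by
#' MM/GS, computes the immune score `IS = sum PC1(B+) - sum PC1(B-)`,
#' dichotomizes it at the survival-optimal cutpoint, and summarizes the
#' prognostic separation (log-rank, fixed-horizon ROC).
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param gene_sets Named list of signature gene sets.
#' @param clinical Clinical table (see [read_clinical()]).
#' @param config A [run_config()] object.
#' @return A list of class `"immunoscore_result"` with elements
#'   `infiltration`, `spearman`, `assignment`, `cluster_logrank`,
#'   `cluster_contrasts`, `soft_threshold`, `modules` (labels), `eigengenes`,
#'   `module_trait`, `mm_gs`, `selected_modules`, `hubs`, `is_table`,
#'   `cutpoint`, `is_logrank`, `roc`, and the `config` used.
#' @export
run_pipeline <- function(expr, gene_sets, clinical, config = run_config()) {
  stopifnot(inherits(config, "is_config"))
  validate_expression_matrix(expr)

  infil <- ssgsea_matrix(expr, gene_sets, alpha = config$alpha,
                         normalize = config$normalize)
  spear <- celltype_spearman(infil)

  X <- nonneg_scale(infil)
  assignment <- select_rank_with_pfs(
    X, clinical, k_range = config$k_range, n_restarts = config$n_restarts,
    seed = config$seed, max_iter = config$max_iter, tol = config$tol,
    stability_floor = config$stability_floor)
  assignment <- label_clusters(assignment, infil)
  clin <- clinical[match(assignment$sample_ids, clinical$sample_id), ]
  cluster_lr <- logrank_test(assignment$labels, clin$pfs_time, clin$pfs_event)
  contrasts <- if (assignment$k == 2L)
    compare_clusters(infil, expr, assignment) else NULL

  n_top <- if (config$n_top > 0L) min(config$n_top, nrow(expr)) else 0L
  fexpr <- filter_genes(expr, n_top)
  sft <- pick_soft_threshold(fexpr, beta_grid = config$beta_grid,
                             target_r2 = config$target_r2)
  adj <- adjacency_matrix(fexpr, sft$beta)
  tom <- tom_similarity(adj)
  labels <- detect_modules(1 - tom, min_size = config$min_module_size,
                           cut_height = config$cut_height)
  if (config$merge_modules)
    labels <- merge_close_modules(fexpr, labels, config$merge_cor)
  eigengenes <- module_eigengenes(fexpr, labels)
  # trait: membership of the lowest-infiltration (immune-cold) cluster —
  # cluster B when k = 2, the coldest cluster otherwise
  cold <- names(which.min(tapply(colMeans(infil)[assignment$sample_ids],
                                 assignment$labels, mean)))
  trait <- stats::setNames(as.numeric(assignment$labels == cold),
                           assignment$sample_ids)
  module_trait <- module_trait_correlation(eigengenes, trait)
  mm_gs <- compute_mm_gs(fexpr, eigengenes, labels, trait)

  selected <- select_modules(module_trait, r_floor = config$r_floor,
                             p_ceiling = config$p_ceiling)
  hubs <- screen_hub_genes(mm_gs, selected, mm_thr = config$mm_thr,
                           gs_thr = config$gs_thr)
  if (nrow(hubs) == 0L) stop("no hub genes survived screening")

  is_table <- compute_immune_score(expr, hubs, pooled = config$pooled_pc1)
  cut <- optimal_cutpoint(is_table, clinical,
                          q_low = config$q_low, q_high = config$q_high)
  grp <- cut$group[is_table$sample_id]
  clin2 <- clinical[match(is_table$sample_id, clinical$sample_id), ]
  is_lr <- logrank_test(grp, clin2$pfs_time, clin2$pfs_event)
  # the fixed-horizon ROC is undefined when one outcome class is empty
  # after excluding early-censored subjects (tiny cohorts); degrade to NA
  roc <- tryCatch(
    roc_horizon(is_table$IS, clin2$pfs_time, clin2$pfs_event,
                horizon_months = config$roc_horizon),
    error = function(e) {
      warning("horizon ROC unavailable: ", conditionMessage(e))
      list(auc = NA_real_, roc = NULL, n_used = 0L, n_excluded = NA_integer_)
    })

  out <- list(infiltration = infil, spearman = spear,
              assignment = assignment, cluster_logrank = cluster_lr,
              cluster_contrasts = contrasts,
              soft_threshold = sft, modules = labels,
              eigengenes = eigengenes, module_trait = module_trait,
              mm_gs = mm_gs, selected_modules = selected, hubs = hubs,
              is_table = is_table, cutpoint = cut, is_logrank = is_lr,
              roc = roc, config = config)
  class(out) <- "immunoscore_result"
  out
}

#' @export
print.immunoscore_result <- function(x, ...) {
  cat("immunoscore pipeline result\n")
  cat(sprintf("  samples: %d   cell types scored: %d\n",
              length(x$assignment$sample_ids), nrow(x$infiltration)))
  cat(sprintf("  chosen NMF rank: %d (cophenetic %.3f)\n",
              x$assignment$k, x$assignment$cophenetic))
  cat(sprintf("  cluster sizes: %s\n",
              paste(sprintf("%s=%d", names(table(x$assignment$labels)),
                            table(x$assignment$labels)), collapse = ", ")))
  cat(sprintf("  cluster PFS log-rank: chisq %.2f, p %.3g\n",
              x$cluster_logrank$chisq, x$cluster_logrank$p))
  n_mod <- length(setdiff(unique(x$modules), "grey"))
  cat(sprintf("  co-expression modules: %d (beta = %g)\n", n_mod,
              x$soft_threshold$beta))
  cat(sprintf("  hub genes: %d in %d module(s)\n", nrow(x$hubs),
              length(unique(x$hubs$module))))
  cat(sprintf("  IS cutpoint: %.4g; high/low log-rank p %.3g; %g-month AUC %.3f\n",
              x$cutpoint$cutpoint, x$is_logrank$p,
              x$config$roc_horizon, x$roc$auc))
  invisible(x)
}
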
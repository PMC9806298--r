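# Run configuration and small internal utilities shared by every stage.

#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the pipeline in one validated list so that a
#' whole analysis is reproducible from `(inputs, config)` alone.  All
#' randomized stages draw their seeds from `seed`; two runs with identical
#' configuration and inputs produce identical outputs.
#'
#' @param alpha ssGSEA rank-weighting exponent (>= 0).
#' @param normalize Logical; min-max rescale the raw enrichment-score matrix
#'   by its global range.
#' @param k_range Integer vector of candidate NMF ranks.
#' @param n_restarts NMF restarts per rank for consensus clustering (>= 2).
#' @param max_iter,tol NMF stopping rule: iteration cap and relative
#'   loss-change tolerance.
#' @param stability_floor Minimum cophenetic coefficient for a rank to be
#'   eligible during survival-informed rank selection.
#' @param n_top Number of most-variable genes kept for network construction
#'   (0 keeps all genes).
#' @param beta_grid Candidate soft-thresholding powers.
#' @param target_r2 Scale-free topology fit targeted when picking the power.
#' @param min_module_size Smallest gene count a module may have.
#' @param cut_height Dendrogram cut height in (0,1), or `NULL` for the
#'   automatic largest-gap rule.
#' @param merge_modules Logical; merge modules whose eigengenes correlate at
#'   or above `merge_cor`.
#' @param merge_cor Eigengene correlation threshold used when merging.
#' @param mm_thr,gs_thr Hub-gene screening thresholds: module membership and
#'   gene significance (strict `>` comparisons).
#' @param r_floor,p_ceiling Module-selection rule: modules with
#'   `|r| >= r_floor` and `p <= p_ceiling` against the cluster trait enter
#'   hub screening.
#' @param q_low,q_high Quantile window searched for the optimal immune-score
#'   cutpoint.
#' @param roc_horizon ROC horizon in months (60 = 5-year progression).
#' @param pooled_pc1 Logical; compute one PC1 per sign group over the pooled
#'   hub genes instead of one PC1 per module.
#' @param seed Integer seed feeding every random stage.
#' @return A list of class `"is_config"`.
#' @export
run_config <- function(alpha = 0.25, normalize = TRUE,
                       k_range = 2:6, n_restarts = 50,
                       max_iter = 2000, tol = 1e-6, stability_floor = 0.95,
                       n_top = 5000, beta_grid = c(1:10, seq(12, 20, 2)),
                       target_r2 = 0.85, min_module_size = 30,
                       cut_height = NULL, merge_modules = FALSE,
                       merge_cor = 0.75,
                       mm_thr = 0.8, gs_thr = 0.5,
                       r_floor = 0.5, p_ceiling = 0.05,
                       q_low = 0.1, q_high = 0.9, roc_horizon = 60,
                       pooled_pc1 = FALSE, seed = 1L) {
  stopifnot(alpha >= 0, is.logical(normalize),
            all(k_range >= 2), n_restarts >= 2,
            max_iter >= 1, tol > 0,
            stability_floor > 0, stability_floor <= 1,
            n_top >= 0, all(beta_grid >= 1),
            target_r2 > 0, target_r2 <= 1, min_module_size >= 3,
            is.null(cut_height) || (cut_height > 0 && cut_height < 1),
            mm_thr > 0, mm_thr < 1, gs_thr > 0, gs_thr < 1,
            r_floor > 0, p_ceiling > 0, p_ceiling <= 1,
            q_low > 0, q_high < 1, q_low < q_high, roc_horizon > 0)
  cfg <- list(alpha = alpha, normalize = normalize,
              k_range = as.integer(k_range), n_restarts = as.integer(n_restarts),
              max_iter = as.integer(max_iter), tol = tol,
              stability_floor = stability_floor,
              n_top = as.integer(n_top), beta_grid = beta_grid,
              target_r2 = target_r2, min_module_size = as.integer(min_module_size),
              cut_height = cut_height, merge_modules = merge_modules,
              merge_cor = merge_cor, mm_thr = mm_thr, gs_thr = gs_thr,
              r_floor = r_floor, p_ceiling = p_ceiling,
              q_low = q_low, q_high = q_high, roc_horizon = roc_horizon,
              pooled_pc1 = pooled_pc1, seed = as.integer(seed))
  class(cfg) <- "is_config"
  cfg
}

# Gated progress/log line.  options(immunoscore.verbose = TRUE) turns it on.
is_log <- function(fmt, ...) {
  if (isTRUE(getOption("immunoscore.verbose", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a stream of child seeds (< 2^31) from a parent seed.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
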
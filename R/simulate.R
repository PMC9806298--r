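# Synthetic cohorts with planted ground truth: two latent infiltration
# groups, signature-driven co-expression modules, checkpoint genes tracking
# mean infiltration, and group-dependent progression-free survival.  Every
# generator is a pure function of (params, seed).

# The 28 immune-cell compartments scored throughout the package.
CELL_TYPES_28 <- c(
  "Activated_CD8_T_cell", "Central_memory_CD8_T_cell",
  "Effector_memory_CD8_T_cell", "Activated_CD4_T_cell",
  "Central_memory_CD4_T_cell", "Effector_memory_CD4_T_cell",
  "T_follicular_helper_cell", "Gamma_delta_T_cell",
  "Type_1_T_helper_cell", "Type_17_T_helper_cell", "Type_2_T_helper_cell",
  "Regulatory_T_cell", "Activated_B_cell", "Immature_B_cell",
  "Memory_B_cell", "Natural_killer_cell",
  "CD56bright_natural_killer_cell", "CD56dim_natural_killer_cell",
  "Myeloid_derived_suppressor_cell", "Natural_killer_T_cell",
  "Activated_dendritic_cell", "Plasmacytoid_dendritic_cell",
  "Immature_dendritic_cell", "Macrophage", "Eosinophil", "Mast_cell",
  "Monocyte", "Neutrophil")

#' Parameters for the synthetic-cohort generator
#'
#' Defaults describe the standing benchmark cohort used throughout the test
#' suite: 400 samples split roughly 39:61 into a high-infiltration group A
#' and a low-infiltration, poorer-prognosis group B (the direction observed
#' in prostate-cancer immune typing), 28 immune-cell signatures of 30 genes
#' each, and exponential progression times with uniform censoring.
#'
#' @param n_samples Cohort size (>= 20).
#' @param n_cell_types Number of immune-cell signatures (max 28 named types).
#' @param genes_per_signature Genes per signature module.
#' @param n_background_genes Unstructured noise genes.
#' @param group_A_fraction Fraction of samples in the high-infiltration
#'   group A.
#' @param infiltration_shift Mean latent infiltration difference A - B
#'   (delta, latent units; > 0).
#' @param infiltration_sd SD of the latent infiltration noise per cell type.
#' @param signature_effect Loading of latent infiltration on signature-gene
#'   expression (beta_sig).
#' @param checkpoint_effect Loading of mean infiltration on the simulated
#'   checkpoint genes CTLA4 and CD274.
#' @param noise_sd Gene-level residual SD on the log2 scale (sigma > 0).
#' @param baseline_hazard Baseline exponential hazard per month (lambda > 0).
#' @param log_hr_B Log hazard ratio of group B versus A on PFS (theta).
#' @param censoring_window Upper bound of the uniform censoring time
#'   (months).
#' @param gleason_assoc,nplus_assoc Added probability of Gleason > 7 and of
#'   N+ status in group B.
#' @param hormone_benefit Log-hazard shift applied to hormone-treated group-A
#'   (high-infiltration, low immune score) samples; negative values plant the
#'   treatment-sensitivity interaction.
#' @param covariate_missing_rate Fraction of optional clinical covariates
#'   blanked to missing.
#' @param seed Integer seed.
#' @return A validated list of class `"sim_params"`.
#' @export
simulation_params <- function(n_samples = 400, n_cell_types = 28,
                              genes_per_signature = 30,
                              n_background_genes = 2000,
                              group_A_fraction = 0.39,
                              infiltration_shift = 3, infiltration_sd = 1.5,
                              signature_effect = 2, checkpoint_effect = 1,
                              noise_sd = 0.5,
                              baseline_hazard = 0.02, log_hr_B = 1,
                              censoring_window = 120,
                              gleason_assoc = 0.25, nplus_assoc = 0.2,
                              hormone_benefit = 0,
                              covariate_missing_rate = 0.02,
                              seed = 1L) {
  stopifnot(n_samples >= 20, n_cell_types >= 1,
            n_cell_types <= length(CELL_TYPES_28),
            genes_per_signature >= 2, n_background_genes >= 0,
            group_A_fraction > 0, group_A_fraction < 1,
            infiltration_shift >= 0, infiltration_sd > 0,
            noise_sd > 0, baseline_hazard > 0, censoring_window > 0,
            gleason_assoc >= 0, gleason_assoc <= 0.6,
            nplus_assoc >= 0, nplus_assoc <= 0.8,
            covariate_missing_rate >= 0, covariate_missing_rate < 1)
  p <- as.list(environment())
  p$n_samples <- as.integer(n_samples)
  p$n_cell_types <- as.integer(n_cell_types)
  p$genes_per_signature <- as.integer(genes_per_signature)
  p$n_background_genes <- as.integer(n_background_genes)
  p$seed <- as.integer(seed)
  class(p) <- "sim_params"
  p
}

#' Simulate latent infiltration for two planted groups
#'
#' Each cell type c of sample s gets `f(c,s) = mu_c + delta * I[group A] +
#' eps`, `eps ~ N(0, infiltration_sd^2)`.  All cell types shift in the same
#' direction, so group A is uniformly more infiltrated and cell types are
#' positively correlated through the shared group factor.
#'
#' @param params A [simulation_params()] object.
#' @return List with `truth` (sample ids, group labels) and `f`
#'   (cell types x samples latent matrix).
#' @export
simulate_infiltration <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_samples
  ct <- CELL_TYPES_28[seq_len(params$n_cell_types)]
  with_seed(params$seed, {
    sample_ids <- sprintf("S%04d", seq_len(n))
    n_A <- max(2L, round(params$group_A_fraction * n))
    if (n - n_A < 2L) n_A <- n - 2L
    group <- rep("B", n)
    group[sample.int(n, n_A)] <- "A"
    mu_c <- stats::rnorm(length(ct), mean = 0, sd = 1)
    f <- matrix(stats::rnorm(length(ct) * n, sd = params$infiltration_sd),
                length(ct), n, dimnames = list(ct, sample_ids))
    f <- f + mu_c + rep(params$infiltration_shift * (group == "A"),
                        each = length(ct))
    list(truth = list(sample_ids = sample_ids,
                      group = stats::setNames(group, sample_ids),
                      mu_c = stats::setNames(mu_c, ct)),
         f = f)
  })
}

#' Simulate a log2 expression matrix from latent infiltration
#'
#' Signature gene g of cell type c: `x(g,s) = b_g + beta_sig * f(c,s) +
#' N(0, sigma^2)`.  Background genes are baseline plus noise.  Two
#' checkpoint genes (`CTLA4`, `CD274`) load positively on the per-sample
#' mean infiltration, so their expression is higher in the
#' high-infiltration group.  The true signatures are returned as a GMT-style
#' gene-set list.
#'
#' @param truth,f Output of [simulate_infiltration()].
#' @param params A [simulation_params()] object.
#' @return List with `expr` (genes x samples matrix), `gene_sets` (named
#'   list), and `gene_module` (named vector: signature name, "background",
#'   or "checkpoint" per gene).
#' @export
simulate_expression <- function(truth, f, params) {
  stopifnot(inherits(params, "sim_params"), is.matrix(f))
  ct <- rownames(f)
  n <- ncol(f)
  gps <- params$genes_per_signature
  with_seed(params$seed + 1L, {
    sig_genes <- unlist(lapply(seq_along(ct), function(i)
      sprintf("SIG%02d_G%02d", i, seq_len(gps))))
    bg_genes <- if (params$n_background_genes > 0)
      sprintf("BG_%04d", seq_len(params$n_background_genes)) else character()
    chk_genes <- c("CTLA4", "CD274")
    genes <- c(sig_genes, bg_genes, chk_genes)
    b_g <- stats::rnorm(length(genes), mean = 6, sd = 1.5)
    expr <- matrix(stats::rnorm(length(genes) * n, sd = params$noise_sd),
                   length(genes), n, dimnames = list(genes, colnames(f)))
    expr <- expr + b_g
    # signature genes track their cell type's latent infiltration
    ct_index <- rep(seq_along(ct), each = gps)
    expr[seq_along(sig_genes), ] <-
      expr[seq_along(sig_genes), ] + params$signature_effect * f[ct_index, ]
    mean_f <- colMeans(f)
    for (g in chk_genes)
      expr[g, ] <- expr[g, ] + params$checkpoint_effect * mean_f
    gene_sets <- stats::setNames(
      lapply(seq_along(ct), function(i) sig_genes[ct_index == i]), ct)
    attr(gene_sets, "descriptions") <-
      stats::setNames(rep("synthetic immune signature", length(ct)), ct)
    gene_module <- stats::setNames(
      c(ct[ct_index], rep("background", length(bg_genes)),
        rep("checkpoint", length(chk_genes))), genes)
    list(expr = expr, gene_sets = gene_sets, gene_module = gene_module)
  })
}

#' Simulate progression-free survival and clinical covariates
#'
#' Event times are exponential with hazard `lambda * exp(theta * I[group B]
#' + hormone_benefit * I[hormone-treated & group A])`; censoring is uniform
#' on `(0, censoring_window]`.  Gleason > 7 and N+ status are enriched in
#' group B by the stated association strengths; therapy flags are assigned
#' independently.
#'
#' @param truth Truth labels from [simulate_infiltration()].
#' @param params A [simulation_params()] object.
#' @return A clinical data.frame as returned by [read_clinical()].
#' @export
simulate_survival <- function(truth, params) {
  stopifnot(inherits(params, "sim_params"))
  ids <- truth$sample_ids
  grp <- truth$group[ids]
  n <- length(ids)
  with_seed(params$seed + 2L, {
    hormone <- stats::rbinom(n, 1L, 0.5)
    radiation <- stats::rbinom(n, 1L, 0.5)
    log_rate <- log(params$baseline_hazard) +
      params$log_hr_B * (grp == "B") +
      params$hormone_benefit * (hormone == 1L & grp == "A")
    event_time <- stats::rexp(n, rate = exp(log_rate))
    cens_time <- stats::runif(n, 0, params$censoring_window)
    pfs_time <- pmax(pmin(event_time, cens_time), 1e-6)
    pfs_event <- as.integer(event_time <= cens_time)
    p_high_gleason <- 0.3 + params$gleason_assoc * (grp == "B")
    high_gl <- stats::rbinom(n, 1L, p_high_gleason) == 1L
    gleason <- ifelse(high_gl, sample(8:10, n, replace = TRUE),
                      sample(6:7, n, replace = TRUE))
    p_nplus <- 0.1 + params$nplus_assoc * (grp == "B")
    n_status <- ifelse(stats::rbinom(n, 1L, p_nplus) == 1L, "N+", "N-")
    t_stage <- sample(paste0("T", 1:4), n, replace = TRUE,
                      prob = c(0.15, 0.35, 0.40, 0.10))
    if (params$covariate_missing_rate > 0) {
      blank <- function(x) {
        x[stats::runif(n) < params$covariate_missing_rate] <- NA
        x
      }
      gleason <- blank(gleason); n_status <- blank(n_status)
      hormone <- blank(hormone); radiation <- blank(radiation)
      t_stage <- blank(t_stage)
    }
    data.frame(sample_id = ids, pfs_time = pfs_time, pfs_event = pfs_event,
               gleason = as.integer(gleason),
               n_status = factor(n_status, levels = c("N-", "N+")),
               hormone_therapy = as.integer(hormone),
               radiation_therapy = as.integer(radiation),
               t_stage = factor(t_stage, levels = paste0("T", 1:4)),
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic cohort
#'
#' Composes [simulate_infiltration()], [simulate_expression()] and
#' [simulate_survival()] into one object carrying the expression matrix,
#' the true signature gene sets, the clinical table and the planted truth.
#'
#' @param params A [simulation_params()] object.
#' @return A list of class `"synthetic_cohort"` with elements `expr`,
#'   `gene_sets`, `clinical`, `truth` (group labels, gene modules, latent
#'   matrix `f`), and `params`.
#' @export
generate_cohort <- function(params = simulation_params()) {
  inf <- simulate_infiltration(params)
  ex <- simulate_expression(inf$truth, inf$f, params)
  clin <- simulate_survival(inf$truth, params)
  out <- list(expr = ex$expr, gene_sets = ex$gene_sets, clinical = clin,
              truth = list(group = inf$truth$group,
                           gene_module = ex$gene_module,
                           f = inf$f),
              params = params)
  class(out) <- "synthetic_cohort"
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `expression.tsv`, `signatures.gmt`, `clinical.tsv` and `truth.tsv`
#' into `dir`, all readable back through the package's readers.
#'
#' @param cohort A [generate_cohort()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$expr, file.path(dir, "expression.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "signatures.gmt"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_df <- data.frame(sample_id = names(cohort$truth$group),
                         group = unname(cohort$truth$group))
  utils::write.table(truth_df, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
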
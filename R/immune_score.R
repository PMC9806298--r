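# The immune score: IS = sum of PC1 scores over modules positively
# correlated with clusterB minus the sum over negatively correlated
# modules, computed from hub-gene expression, then dichotomized at the
# survival-optimal cutpoint.

#' Sign-oriented first principal component of a gene subset
#'
#' Genes are z-scored across samples; the score is the first principal
#' component's raw sample scores (variance equal to the leading eigenvalue,
#' no unit-variance rescaling), sign-oriented to correlate positively with
#' the mean standardized expression of the subset.  Without the orientation
#' rule the PCA sign — and hence the immune score — would be arbitrary.
#'
#' @param expr Genes x samples matrix.
#' @param genes Gene subset (>= 2 genes present in `expr`).
#' @return Named numeric vector of per-sample scores.
#' @export
signed_pc1 <- function(expr, genes) {
  present <- intersect(genes, rownames(expr))
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance gene(s) from PC1")
    sub <- sub[sds > 0, , drop = FALSE]
  }
  if (nrow(sub) < 2L) stop("need >= 2 usable genes for PC1")
  z <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
  sv <- svd(z, nu = 0L, nv = 1L)
  scores <- sv$d[1L] * sv$v[, 1L]
  if (stats::cor(scores, colMeans(z)) < 0) scores <- -scores
  stats::setNames(scores, colnames(expr))
}

#' Compute the immune score from hub genes
#'
#' Per module, computes [signed_pc1()] on its hub genes; per-sample scores
#' are then summed within each trait sign and combined as
#' `IS = sum(PC1, B+ modules) - sum(PC1, B- modules)`.  A missing side
#' contributes 0 (with a warning); both sides empty is an error.  With
#' `pooled = TRUE` one PC1 is computed per sign over the pooled hub genes
#' instead (this coincides with the default when each sign has one module).
#'
#' @param expr Genes x samples expression matrix.
#' @param hubs A `"hub_gene_set"` from [screen_hub_genes()] (columns `gene`,
#'   `module`, `sign`).
#' @param pooled Logical; pool hub genes per sign into a single PCA.
#' @return Data.frame of class `"immune_score_table"` with columns
#'   `sample_id`, `pc1_Bpos`, `pc1_Bneg`, `IS`.
#' @export
compute_immune_score <- function(expr, hubs, pooled = FALSE) {
  stopifnot(all(c("gene", "module", "sign") %in% colnames(hubs)))
  side <- function(sgn) {
    sub <- hubs[hubs$sign == sgn, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    if (pooled) return(signed_pc1(expr, unique(sub$gene)))
    mods <- unique(sub$module)
    Reduce(`+`, lapply(mods, function(m)
      signed_pc1(expr, sub$gene[sub$module == m])))
  }
  pos <- side("B+")
  neg <- side("B-")
  if (is.null(pos) && is.null(neg)) stop("no hub genes on either side")
  if (is.null(pos)) { warning("no B+ modules; their sum is 0")
    pos <- stats::setNames(numeric(ncol(expr)), colnames(expr)) }
  if (is.null(neg)) { warning("no B- modules; their sum is 0")
    neg <- stats::setNames(numeric(ncol(expr)), colnames(expr)) }
  out <- data.frame(sample_id = colnames(expr), pc1_Bpos = unname(pos),
                    pc1_Bneg = unname(neg), IS = unname(pos - neg),
                    stringsAsFactors = FALSE)
  class(out) <- c("immune_score_table", "data.frame")
  out
}

#' Survival-optimal immune-score cutpoint
#'
#' Maximally selected log-rank cutpoint: candidates are the observed scores
#' inside the `[q_low, q_high]` quantile window; for each, samples are split
#' at `IS > cutpoint` and the two-group log-rank chi-square on PFS is
#' computed.  The candidate with the largest statistic wins; ties go to the
#' more balanced split, then the lower value.  The associated p-value is
#' selection-inflated and reported as descriptive only.
#'
#' @param scores An `"immune_score_table"` or a named numeric vector of
#'   per-sample scores.
#' @param clinical Clinical table covering the scored samples.
#' @param q_low,q_high Quantile window searched (defaults 0.1 and 0.9).
#' @return List with `cutpoint`, `group` (named factor `high`/`low`),
#'   `chisq`, `p` (descriptive), and `search` (per-candidate diagnostics).
#' @export
optimal_cutpoint <- function(scores, clinical, q_low = 0.1, q_high = 0.9) {
  if (inherits(scores, "immune_score_table"))
    scores <- stats::setNames(scores$IS, scores$sample_id)
  stopifnot(q_low > 0, q_high < 1, q_low < q_high)
  ids <- names(scores)
  miss <- setdiff(ids, clinical$sample_id)
  if (length(miss)) stop("clinical table missing sample(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  clin <- clinical[match(ids, clinical$sample_id), ]
  qs <- stats::quantile(scores, c(q_low, q_high), names = FALSE)
  cand <- sort(unique(scores[scores >= qs[1L] & scores <= qs[2L]]))
  # a cut at the largest candidate would leave the high group empty
  cand <- cand[cand < max(scores)]
  if (length(cand) == 0L) stop("no usable cutpoint candidate in the window")
  rows <- lapply(cand, function(cp) {
    high <- scores > cp
    ev_hi <- sum(clin$pfs_event[high]); ev_lo <- sum(clin$pfs_event[!high])
    if (ev_hi == 0L || ev_lo == 0L) return(NULL)
    lr <- logrank_test(ifelse(high, "high", "low"),
                       clin$pfs_time, clin$pfs_event)
    data.frame(cutpoint = cp, chisq = lr$chisq, p = lr$p,
               n_high = sum(high), n_low = sum(!high))
  })
  search <- do.call(rbind, rows)
  if (is.null(search) || nrow(search) == 0L)
    stop("no candidate yields two event-bearing groups")
  imbalance <- abs(search$n_high - search$n_low)
  best <- order(-search$chisq, imbalance, search$cutpoint)[1L]
  cp <- search$cutpoint[best]
  group <- factor(ifelse(scores > cp, "high", "low"),
                  levels = c("high", "low"))
  names(group) <- ids
  is_log("optimal_cutpoint: cutpoint %.4g (chisq %.2f; selection-inflated p %.3g)",
         cp, search$chisq[best], search$p[best])
  list(cutpoint = cp, group = group, chisq = search$chisq[best],
       p = search$p[best], search = search)
}
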
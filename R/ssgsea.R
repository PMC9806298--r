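# Single-sample gene set enrichment (ssGSEA) scoring of immune-cell
# signatures, plus the Spearman co-occurrence matrix of the scored cell
# types.  The enrichment walk is the Barbie-style two-ECDF form: rank-power
# weighted steps inside the set against uniform steps outside it.

#' Rank-transform an expression matrix per sample
#'
#' Within each sample, genes are ranked by expression with rank 1 for the
#' lowest value and average ranks for ties.  Any strictly increasing
#' transformation of a sample's values leaves its ranks unchanged, which is
#' what makes the enrichment score robust to sample-level normalization.
#'
#' @param expr Numeric genes x samples matrix.
#' @return Matrix of the same shape holding per-sample ranks.
#' @export
rank_transform <- function(expr) {
  validate_expression_matrix(expr)
  apply(expr, 2L, rank, ties.method = "average")
}

#' Enrichment score of one gene set in one sample
#'
#' Walk the genes of a sample in decreasing rank order.  At an in-set gene
#' the in-set running fraction increases by `rank^alpha / sum(rank^alpha over
#' the set)`; at an out-of-set gene the out-set fraction increases by
#' `1/(N - |S|)`.  The score is the sum over all positions of the difference
#' between the two running fractions, so coordinately high sets score
#' positive and coordinately low sets negative.
#'
#' @param sample_ranks Named numeric vector of per-gene ranks for one sample.
#' @param gene_set Character vector of gene ids.
#' @param alpha Rank-weighting exponent (>= 0); `alpha = 0` weights all
#'   in-set genes equally.
#' @return A single numeric enrichment score.
#' @export
enrichment_score <- function(sample_ranks, gene_set, alpha = 0.25) {
  stopifnot(is.numeric(sample_ranks), !is.null(names(sample_ranks)),
            alpha >= 0)
  inset <- names(sample_ranks) %in% gene_set
  n_in <- sum(inset)
  if (n_in == 0L) stop("gene set has empty intersection with the ranked genes")
  if (n_in == length(sample_ranks))
    stop("gene set covers all ranked genes; out-of-set ECDF undefined")
  ord <- order(sample_ranks, decreasing = TRUE)
  r <- sample_ranks[ord]
  m <- inset[ord]
  w <- ifelse(m, r^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!m) / (length(r) - n_in)
  sum(p_in - p_out)
}

#' ssGSEA score matrix over a gene-set collection
#'
#' Scores every (set, sample) pair.  Genes of a set absent from the matrix
#' are intersected out (the effective set size is logged); a set with no
#' genes left is an error.  With `normalize = TRUE` the raw matrix is
#' divided by its global range (max - min), an order-preserving affine
#' rescaling.
#'
#' @param expr Numeric genes x samples matrix.
#' @param sets Named list of gene-id vectors (see [read_gmt()]).
#' @param alpha Rank-weighting exponent.
#' @param normalize Logical; apply the global min-max rescaling.
#' @return Numeric cell-types x samples matrix with attributes `alpha` and
#'   `normalized`.
#' @export
ssgsea_matrix <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  validate_expression_matrix(expr)
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  eff <- lapply(sets, intersect, x = rownames(expr))
  empty <- names(sets)[lengths(eff) == 0L]
  if (length(empty))
    stop("gene set(s) with no genes in the matrix: ",
         paste(empty, collapse = ", "))
  for (nm in names(sets))
    if (length(eff[[nm]]) < length(unique(sets[[nm]])))
      is_log("ssgsea_matrix: set '%s' effective size %d of %d", nm,
             length(eff[[nm]]), length(unique(sets[[nm]])))
  ranks <- rank_transform(expr)
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  n <- nrow(ranks)
  for (s in seq_len(ncol(ranks))) {
    rs <- ranks[, s]
    ord <- order(rs, decreasing = TRUE)
    r_sorted <- rs[ord]
    genes_sorted <- rownames(ranks)[ord]
    for (j in seq_along(eff)) {
      m <- genes_sorted %in% eff[[j]]
      w <- ifelse(m, r_sorted^alpha, 0)
      scores[j, s] <- sum(cumsum(w) / sum(w) - cumsum(!m) / (n - sum(m)))
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "normalized") <- normalize
  scores
}

#' Spearman co-occurrence of scored cell types
#'
#' Pairwise Spearman rank correlation between the rows of an infiltration
#' matrix, with two-sided t-approximation p-values.  Constant rows yield
#' missing correlations for their pairs (logged).
#'
#' @param infil Cell-types x samples score matrix.
#' @return List with `rho` and `p`, both cell-type square matrices.
#' @export
celltype_spearman <- function(infil) {
  stopifnot(is.matrix(infil), ncol(infil) >= 3L)
  const <- apply(infil, 1L, function(x) stats::sd(x) == 0)
  if (any(const))
    is_log("celltype_spearman: %d constant cell type(s); correlations set missing",
           sum(const))
  rho <- suppressWarnings(stats::cor(t(infil), method = "spearman"))
  n <- ncol(infil)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  list(rho = rho, p = p)
}
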
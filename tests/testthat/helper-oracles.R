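# Independent brute-force oracles used to cross-check the package's
# implementations.  These are deliberately written as plain loops over the
# defining formulas, not shared with the package code.

# Two-ECDF enrichment walk: explicit running empirical CDFs.
oracle_enrichment_score <- function(sample_ranks, gene_set, alpha) {
  genes <- names(sample_ranks)
  in_set <- genes %in% gene_set
  walk <- order(sample_ranks, decreasing = TRUE)
  denom_in <- sum(sample_ranks[in_set]^alpha)
  denom_out <- sum(!in_set)
  ecdf_in <- 0
  ecdf_out <- 0
  es <- 0
  for (pos in walk) {
    if (in_set[pos]) {
      ecdf_in <- ecdf_in + sample_ranks[pos]^alpha / denom_in
    } else {
      ecdf_out <- ecdf_out + 1 / denom_out
    }
    es <- es + (ecdf_in - ecdf_out)
  }
  unname(es)
}

# Topological overlap by the defining triple loop.
oracle_tom <- function(adj) {
  p <- nrow(adj)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) { out[i, j] <- 1; next }
      l_ij <- 0
      for (u in seq_len(p)) {
        if (u != i && u != j) l_ij <- l_ij + adj[i, u] * adj[u, j]
      }
      k_i <- sum(adj[i, -i])
      k_j <- sum(adj[j, -j])
      out[i, j] <- (l_ij + adj[i, j]) / (min(k_i, k_j) + 1 - adj[i, j])
    }
  }
  out
}

# Exhaustive maximal-clique enumeration over all vertex subsets (n <= ~15),
# returning the MCC score per node.
oracle_mcc <- function(adj_logical) {
  n <- nrow(adj_logical)
  nodes <- rownames(adj_logical)
  score <- stats::setNames(numeric(n), nodes)
  for (size in 2:n) {
    for (subset in utils::combn(n, size, simplify = FALSE)) {
      pairs <- utils::combn(subset, 2L)
      is_clique <- all(adj_logical[cbind(pairs[1L, ], pairs[2L, ])])
      if (!is_clique) next
      outside <- setdiff(seq_len(n), subset)
      maximal <- !any(vapply(outside, function(v)
        all(adj_logical[v, subset]), logical(1L)))
      if (maximal) score[subset] <- score[subset] + factorial(size - 1L)
    }
  }
  score
}

# AUC as the concordant-pair fraction (ties count one half).
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# Exact two-sided rank-sum p by complete enumeration of group assignments.
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  us <- vapply(utils::combn(length(pooled), m, simplify = FALSE),
               function(idx) sum(r[idx]) - m * (m + 1) / 2, numeric(1L))
  mu <- m * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
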
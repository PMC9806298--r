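# Consensus non-negative matrix factorization of the infiltration matrix,
# with survival-informed rank selection: candidate ranks are screened for
# factorization stability (cophenetic coefficient) and the progression-free
# survival log-rank statistic breaks the choice among the stable ones.
# Clusters are then given A/B semantics by infiltration level (A = high).

#' Min-max scale each cell-type row to [0, 1]
#'
#' NMF needs non-negative input; enrichment scores are interval-scale, so a
#' per-row affine rescaling preserves every sample ordering while making the
#' matrix non-negative.
#'
#' @param infil Cell-types x samples score matrix.
#' @return Matrix of the same shape with every row spanning [0, 1].
#' @export
nonneg_scale <- function(infil) {
  stopifnot(is.matrix(infil), is.numeric(infil))
  rng <- t(apply(infil, 1L, range))
  const <- rng[, 2L] - rng[, 1L] == 0
  if (any(const))
    stop("constant cell-type row(s): ",
         paste(rownames(infil)[const], collapse = ", "))
  (infil - rng[, 1L]) / (rng[, 2L] - rng[, 1L])
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius objective `||X - WH||^2` with the classic
#' multiplicative update rules, which guarantee a non-increasing loss.
#' Stops when the relative loss change falls below `tol` or after
#' `max_iter` iterations.
#'
#' @param X Non-negative m x n matrix.
#' @param k Factorization rank, `2 <= k < min(m, n)`.
#' @param seed Seed for the uniform random initialization.
#' @param max_iter Iteration cap.
#' @param tol Relative loss-change stopping tolerance.
#' @return List with `W` (m x k), `H` (k x n), `loss` (per-iteration trace)
#'   and `iterations`.
#' @export
nmf_factorize <- function(X, k, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  stopifnot(is.matrix(X), all(X >= 0), !anyNA(X))
  m <- nrow(X); n <- ncol(X)
  if (k < 2L || k >= min(m, n))
    stop("rank k must satisfy 2 <= k < min(dim(X)) = ", min(m, n))
  eps <- .Machine$double.eps
  init <- with_seed(seed, list(W = matrix(stats::runif(m * k), m, k),
                               H = matrix(stats::runif(k * n), k, n)))
  W <- init$W; H <- init$H
  loss <- numeric(0L)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * crossprod(W, X) / (crossprod(W) %*% H + eps)
    W <- W * tcrossprod(X, H) / (W %*% tcrossprod(H) + eps)
    cur <- sum((X - W %*% H)^2)
    loss <- c(loss, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(prev, eps)) break
    prev <- cur
  }
  dimnames(W) <- list(rownames(X), NULL)
  dimnames(H) <- list(NULL, colnames(X))
  list(W = W, H = H, loss = loss, iterations = length(loss))
}

# Per-restart sample labels from the factor-activity matrix H: whiten the
# sample coordinates (unique up to rotation, which k-means ignores) and run
# seeded k-means.  Falls back to unwhitened coordinates if the covariance
# is singular (e.g. duplicated samples only).
factor_space_labels <- function(H, k, seed, nstart = 20L) {
  ht <- t(H)
  cv <- stats::cov(ht)
  eig <- eigen(cv, symmetric = TRUE)
  # directions with relative variance below 1e-6 are numerical jitter of
  # the converged factorization; whitening must not inflate them
  pos <- eig$values > 1e-6 * max(eig$values, 0)
  coords <- if (sum(pos) >= 1L)
    ht %*% eig$vectors[, pos, drop = FALSE] %*%
      diag(1 / sqrt(eig$values[pos]), sum(pos))
  else ht
  with_seed(seed, stats::kmeans(coords, centers = k, nstart = nstart)$cluster)
}

#' Consensus clustering by repeated NMF restarts
#'
#' Each restart factorizes `X` from a fresh random start and clusters the
#' samples in factor-activity space: the columns of `H` are whitened and
#' partitioned by k-means.  Whitening makes the assignment invariant to the
#' scale/shear indeterminacy of the factor pair (any invertible `A` gives
#' the same fit via `W A^-1, A H`), which a raw per-column argmax is not —
#' argmax fails outright when one cluster's profile dominates the other's
#' on every row, as immune-hot versus immune-cold samples do.  The
#' consensus matrix holds the fraction of restarts co-assigning each sample
#' pair; final labels come from average-linkage hierarchical clustering of
#' `1 - consensus` cut into `k` groups, and the cophenetic coefficient
#' (correlation of consensus distances with the dendrogram's cophenetic
#' distances) measures stability.
#'
#' @param X Non-negative cell-types x samples matrix.
#' @param k Number of clusters / factorization rank.
#' @param n_restarts Number of random restarts (>= 2).
#' @param seed Seed controlling all restarts.
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @param retry_cap Re-runs allowed for restarts that leave a factor empty.
#' @return List with `labels` (integer 1..k per sample), `consensus`,
#'   `cophenetic`, `pac` (proportion of consensus entries in (0.1, 0.9) —
#'   the proportion of ambiguous clustering, 0 for perfectly reproducible
#'   partitions), and `hclust` (the consensus dendrogram).
#' @export
consensus_cluster <- function(X, k, n_restarts = 50L, seed = 1L,
                              max_iter = 2000L, tol = 1e-6,
                              retry_cap = 10L) {
  stopifnot(n_restarts >= 2L)
  n <- ncol(X)
  seeds <- child_seeds(seed, n_restarts * (retry_cap + 1L))
  consensus <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
  next_seed <- n_restarts
  for (r in seq_len(n_restarts)) {
    lab <- NULL
    s <- seeds[r]
    for (try in 0:retry_cap) {
      fit <- nmf_factorize(X, k, seed = s, max_iter = max_iter, tol = tol)
      cand <- tryCatch(factor_space_labels(fit$H, k, seed = s),
                       error = function(e) integer(0L))
      if (length(unique(cand)) == k) { lab <- cand; break }
      next_seed <- next_seed + 1L
      s <- seeds[next_seed]
    }
    if (is.null(lab))
      stop("restart ", r, " produced an empty cluster after ", retry_cap,
           " retries")
    consensus <- consensus + outer(lab, lab, "==")
  }
  consensus <- consensus / n_restarts
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  coph <- suppressWarnings(stats::cor(d, stats::cophenetic(hc)))
  if (is.na(coph)) coph <- 1  # degenerate: all consensus distances equal
  off <- consensus[upper.tri(consensus)]
  pac <- mean(off > 0.1 & off < 0.9)  # proportion of ambiguous clustering
  list(labels = stats::setNames(labels, colnames(X)), consensus = consensus,
       cophenetic = coph, pac = pac, hclust = hc)
}

#' Survival-informed NMF rank selection
#'
#' For each candidate rank, runs consensus clustering and computes the
#' k-group log-rank chi-square on progression-free survival.  A rank is
#' eligible when its partition is reproducible across restarts: cophenetic
#' coefficient at least `stability_floor` and proportion of ambiguous
#' clustering (PAC, the fraction of consensus entries strictly between 0.1
#' and 0.9) at most `pac_ceiling`.  If no rank qualifies, the most stable
#' one (smallest PAC, then largest cophenetic) is used.  Among eligible
#' ranks the one with the strongest log-rank separation — the smallest
#' p-value, which unlike the raw chi-square is comparable across group
#' counts with different degrees of freedom — is chosen, ties going to the
#' smaller rank.  Survival thus enters model selection only, never the
#' factorization objective itself.
#'
#' @param X Non-negative cell-types x samples matrix (see [nonneg_scale()]).
#' @param clinical Clinical table containing every sample of `X`.
#' @param k_range Candidate ranks (integers >= 2).
#' @param n_restarts,seed,max_iter,tol Passed to [consensus_cluster()].
#' @param stability_floor Minimum cophenetic coefficient for eligibility.
#' @param pac_ceiling Maximum proportion of ambiguous clustering for
#'   eligibility.
#' @return A list of class `"cluster_assignment"`: `sample_ids`, `labels`
#'   (factor `C1..Ck`), `k`, `diagnostics` (per-rank cophenetic and log-rank
#'   columns), `consensus` for the chosen rank, and `seed`.
#' @export
select_rank_with_pfs <- function(X, clinical, k_range = 2:6,
                                 n_restarts = 50L, seed = 1L,
                                 max_iter = 2000L, tol = 1e-6,
                                 stability_floor = 0.95,
                                 pac_ceiling = 0.1) {
  if (length(k_range) == 0L) stop("k_range is empty")
  miss <- setdiff(colnames(X), clinical$sample_id)
  if (length(miss))
    stop("clinical table missing sample(s): ", paste(miss, collapse = ", "))
  clin <- clinical[match(colnames(X), clinical$sample_id), ]
  seeds <- child_seeds(seed, length(k_range))
  runs <- vector("list", length(k_range))
  diag_df <- data.frame(k = as.integer(k_range), cophenetic = NA_real_,
                        pac = NA_real_,
                        logrank_chisq = NA_real_, logrank_p = NA_real_)
  for (i in seq_along(k_range)) {
    cc <- consensus_cluster(X, k_range[i], n_restarts = n_restarts,
                            seed = seeds[i], max_iter = max_iter, tol = tol)
    lr <- logrank_test(cc$labels, clin$pfs_time, clin$pfs_event)
    diag_df$cophenetic[i] <- cc$cophenetic
    diag_df$pac[i] <- cc$pac
    diag_df$logrank_chisq[i] <- lr$chisq
    diag_df$logrank_p[i] <- lr$p
    runs[[i]] <- cc
  }
  eligible <- which(diag_df$cophenetic >= stability_floor &
                    diag_df$pac <= pac_ceiling)
  if (length(eligible) == 0L) {
    eligible <- order(diag_df$pac, -diag_df$cophenetic)[1L]
    is_log("select_rank_with_pfs: no rank met the stability screen; using most stable")
  }
  best <- eligible[order(diag_df$logrank_p[eligible],
                         diag_df$k[eligible])[1L]]
  chosen <- runs[[best]]
  k <- diag_df$k[best]
  out <- list(sample_ids = colnames(X),
              labels = factor(paste0("C", chosen$labels),
                              levels = paste0("C", seq_len(k))),
              k = k, diagnostics = diag_df, consensus = chosen$consensus,
              cophenetic = chosen$cophenetic, seed = as.integer(seed))
  class(out) <- "cluster_assignment"
  out
}

#' Name the two clusters by infiltration level
#'
#' With `k = 2`, the cluster with the higher grand-mean infiltration becomes
#' `A` (the immune-hot, better-prognosis type) and the other `B`.  An exact
#' tie is broken deterministically: `A` is the cluster containing the
#' lexicographically smallest sample id (with a warning).  For `k != 2` the
#' `C1..Ck` labels are kept with a warning.
#'
#' @param assignment A `"cluster_assignment"` object.
#' @param infil The (raw or scaled) infiltration matrix used for clustering.
#' @return The assignment with `labels` releveled to `A`/`B`.
#' @export
label_clusters <- function(assignment, infil) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (assignment$k != 2L) {
    warning("A/B semantics need k = 2; keeping C1..Ck labels")
    return(assignment)
  }
  lab <- assignment$labels
  means <- tapply(colMeans(infil)[assignment$sample_ids], lab, mean)
  if (means[1L] == means[2L]) {
    warning("clusters have equal mean infiltration; tie broken by sample id")
    first <- lab[order(assignment$sample_ids)][1L]
    ab <- if (levels(lab)[1L] == first) c("A", "B") else c("B", "A")
  } else {
    ab <- if (means[1L] > means[2L]) c("A", "B") else c("B", "A")
  }
  assignment$labels <- factor(ab[as.integer(lab)], levels = c("A", "B"))
  names(assignment$labels) <- assignment$sample_ids
  assignment
}

#' Wilcoxon contrasts of cell abundances and selected genes between clusters
#'
#' For each cell type (rows of `infil`) and each requested gene, performs a
#' two-sided Wilcoxon rank-sum test between the two clusters and records
#' which cluster has the higher median.  Requested genes absent from the
#' matrix are recorded as missing.
#'
#' @param infil Cell-types x samples score matrix.
#' @param expr Genes x samples expression matrix.
#' @param assignment A two-cluster `"cluster_assignment"`.
#' @param gene_list Genes to contrast (e.g. checkpoint genes `CTLA4`,
#'   `CD274`).
#' @return Data.frame with columns `feature`, `kind`, `statistic`, `p`,
#'   `higher_in`.
#' @export
compare_clusters <- function(infil, expr, assignment,
                             gene_list = c("CTLA4", "CD274")) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  lab <- assignment$labels
  lv <- levels(droplevels(lab))
  if (length(lv) != 2L) stop("compare_clusters needs exactly two clusters")
  g1 <- assignment$sample_ids[lab == lv[1L]]
  g2 <- assignment$sample_ids[lab == lv[2L]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each cluster needs >= 2 samples")
  one <- function(vals, feature, kind) {
    wt <- wilcoxon_rank_sum(vals[g1], vals[g2])
    data.frame(feature = feature, kind = kind, statistic = wt$statistic,
               p = wt$p,
               higher_in = lv[if (stats::median(vals[g1]) >=
                                  stats::median(vals[g2])) 1L else 2L],
               stringsAsFactors = FALSE)
  }
  rows <- lapply(rownames(infil), function(ct)
    one(infil[ct, ], ct, "cell_type"))
  for (g in gene_list) {
    if (!g %in% rownames(expr)) {
      is_log("compare_clusters: gene '%s' absent from matrix", g)
      rows <- c(rows, list(data.frame(feature = g, kind = "gene",
                                      statistic = NA_real_, p = NA_real_,
                                      higher_in = NA_character_,
                                      stringsAsFactors = FALSE)))
    } else {
      rows <- c(rows, list(one(expr[g, ], g, "gene")))
    }
  }
  do.call(rbind, rows)
}
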
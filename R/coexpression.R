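# Weighted co-expression network analysis: soft-thresholded unsigned
# adjacency, topological overlap, average-linkage module detection with a
# fixed-height cut, module eigengenes, module-trait correlation, and the
# per-gene module-membership (MM) and gene-significance (GS) statistics
# used downstream for hub screening.

MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Keep the most variable genes
#'
#' Ranks genes by median absolute deviation across samples and keeps the top
#' `n_top` (0 keeps everything).  Constant genes (MAD 0) are never selected
#' while more variable genes remain.
#'
#' @param expr Genes x samples matrix.
#' @param n_top Number of genes to keep; 0 = identity.
#' @return The filtered matrix, rows ordered by decreasing MAD.
#' @export
filter_genes <- function(expr, n_top = 5000L) {
  validate_expression_matrix(expr)
  if (n_top == 0L) return(expr)
  stopifnot(n_top <= nrow(expr))
  mads <- apply(expr, 1L, stats::mad)
  ord <- order(mads, decreasing = TRUE)
  expr[ord[seq_len(n_top)], , drop = FALSE]
}

#' Pick the soft-thresholding power by scale-free fit
#'
#' For each candidate power `beta`, builds the unsigned adjacency
#' `|cor|^beta`, computes each gene's connectivity `k_i`, bins the
#' connectivities (about 10 equal-width bins), and regresses
#' `log10(frequency)` on `log10(mean k)`.  The fit is the regression R^2,
#' sign-flipped to negative when the slope is positive (scale-free topology
#' requires a decreasing law).  The chosen power is the smallest reaching
#' `target_r2`, or the best-fitting one with a warning if none does.
#'
#' @param expr Genes x samples matrix (pre-filtered).
#' @param beta_grid Candidate integer powers >= 1.
#' @param target_r2 Scale-free fit target (default 0.85).
#' @param n_bins Connectivity histogram bins.
#' @return List with `beta` and `fit_table` (power, fit, mean/median/max
#'   connectivity).
#' @export
pick_soft_threshold <- function(expr, beta_grid = c(1:10, seq(12, 20, 2)),
                                target_r2 = 0.85, n_bins = 10L) {
  stopifnot(length(beta_grid) >= 1L, all(beta_grid >= 1))
  if (nrow(expr) < 30L) stop("too few genes for a connectivity histogram")
  cors <- abs(stats::cor(t(expr)))
  if (anyNA(cors)) stop("constant gene(s); filter before thresholding")
  diag(cors) <- 0
  fit_one <- function(beta) {
    k <- rowSums(cors^beta)
    brk <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    meank <- tapply(k, bin, mean)
    ok <- !is.na(freq) & freq > 0 & meank > 0
    if (sum(ok) < 3L)
      return(c(fit = NA_real_, mean_k = mean(k),
               median_k = stats::median(k), max_k = max(k)))
    lf <- log10(freq[ok]); lk <- log10(meank[ok])
    fit <- stats::lm(lf ~ lk)
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2L]
    c(fit = if (slope > 0) -r2 else r2, mean_k = mean(k),
      median_k = stats::median(k), max_k = max(k))
  }
  tab <- t(vapply(beta_grid, fit_one, numeric(4L)))
  fit_table <- data.frame(beta = beta_grid, tab)
  if (all(is.na(fit_table$fit))) {
    beta <- beta_grid[which.min(abs(beta_grid - 6))]
    warning("connectivity histogram degenerate at every power; falling back to beta = ",
            beta)
    return(list(beta = beta, fit_table = fit_table))
  }
  hit <- which(!is.na(fit_table$fit) & fit_table$fit >= target_r2)
  if (length(hit)) {
    beta <- beta_grid[hit[1L]]
  } else {
    # a failed scale-free fit carries no signal about the right power, so
    # fall back to the conventional unsigned-network default (6), clamped
    # to the supplied grid
    beta <- beta_grid[which.min(abs(beta_grid - 6))]
    warning(sprintf("no power reached scale-free fit %.2f (best %.2f); falling back to the conventional beta = %g",
                    target_r2, max(fit_table$fit, na.rm = TRUE), beta))
  }
  list(beta = beta, fit_table = fit_table)
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` with unit diagonal.
#'
#' @param expr Genes x samples matrix.
#' @param beta Soft-thresholding power (>= 1).
#' @return Symmetric gene x gene matrix in [0, 1].
#' @export
adjacency_matrix <- function(expr, beta) {
  stopifnot(beta >= 1)
  cors <- suppressWarnings(stats::cor(t(expr)))
  if (anyNA(cors)) {
    const <- rownames(expr)[apply(expr, 1L, stats::sd) == 0]
    stop("constant gene(s): ", paste(const, collapse = ", "))
  }
  adj <- abs(cors)^beta
  diag(adj) <- 1
  adj
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `L_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` is node connectivity;
#' `TOM_ii = 1`.  Two genes overlap strongly when they share weighted
#' neighbourhoods, which denoises the raw adjacency before clustering.
#'
#' @param adj Adjacency matrix from [adjacency_matrix()].
#' @return Symmetric TOM matrix in [0, 1].
#' @export
tom_similarity <- function(adj) {
  stopifnot(is.matrix(adj), isSymmetric(unname(adj)))
  a <- adj
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a fixed
#' height.  With `cut_height = NULL` the height is placed in the middle of
#' the largest gap between consecutive merge heights in the upper half of
#' the dendrogram — a deterministic rule that lands between the tight
#' within-module merges and the late between-module ones.  Clusters smaller
#' than `min_size` become `"grey"` (unassigned); surviving modules are named
#' by decreasing size with the conventional colour names.
#'
#' @param dissTOM Gene x gene dissimilarity (`1 - TOM`).
#' @param min_size Minimum module size (>= 3).
#' @param cut_height Fixed cut height in (0, 1), or `NULL` for the automatic
#'   largest-gap rule.
#' @return Named character vector of module colours per gene, with the used
#'   cut height in attribute `cut_height`.
#' @export
detect_modules <- function(dissTOM, min_size = 30L, cut_height = NULL) {
  stopifnot(is.matrix(dissTOM), min_size >= 3L)
  hc <- stats::hclust(stats::as.dist(dissTOM), method = "average")
  if (is.null(cut_height)) {
    h <- sort(hc$height)
    upper <- h[h >= stats::median(h)]
    gaps <- diff(upper)
    i <- which.max(gaps)
    cut_height <- (upper[i] + upper[i + 1L]) / 2
  } else stopifnot(cut_height > 0, cut_height < 1)
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  labels <- rep("grey", length(raw))
  if (length(keep) == 0L) {
    warning("all genes unassigned (grey): no cluster reached min_size")
  } else {
    # name surviving modules by decreasing size; exact ties broken by the
    # smallest gene index for determinism
    first_idx <- vapply(keep, function(cl) which(raw == cl)[1L], integer(1L))
    ord <- keep[order(-as.integer(sizes[as.character(keep)]), first_idx)]
    for (j in seq_along(ord)) {
      nm <- if (j <= length(MODULE_COLORS)) MODULE_COLORS[j]
            else paste0("module", j)
      labels[raw == ord[j]] <- nm
    }
  }
  names(labels) <- hc$labels
  attr(labels, "cut_height") <- cut_height
  labels
}

#' Module eigengenes
#'
#' Per module: genes are z-scored across samples, and the eigengene is the
#' first principal component's sample scores, rescaled to unit variance and
#' sign-oriented so it correlates positively with the module's mean
#' standardized profile.  Grey (unassigned) genes are skipped; zero-variance
#' genes are dropped from their module's PC with a warning.
#'
#' @param expr Genes x samples matrix.
#' @param labels Module labels from [detect_modules()].
#' @return Modules x samples eigengene matrix (zero mean, unit variance per
#'   row).
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0L) stop("no non-grey modules")
  eg <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(mods, colnames(expr)))
  for (m in mods) {
    genes <- names(labels)[labels == m]
    if (length(genes) < 2L) stop("module '", m, "' has fewer than 2 genes")
    sub <- expr[genes, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " zero-variance gene(s) from module ", m)
      sub <- sub[sds > 0, , drop = FALSE]
    }
    z <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    eg[m, ] <- e / stats::sd(e)
  }
  eg
}

#' Correlate module eigengenes with a binary trait
#'
#' Pearson correlation of each eigengene with a 0/1 trait (here, membership
#' of the poor-prognosis clusterB), with two-sided t-approximation p-values.
#'
#' @param eigengenes Modules x samples matrix.
#' @param trait Numeric or logical 0/1 vector, one value per sample (named
#'   or in column order).
#' @return Data.frame with columns `module`, `r`, `p`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  trait <- align_trait(trait, colnames(eigengenes))
  if (stats::sd(trait) == 0) stop("trait is constant")
  n <- length(trait)
  r <- apply(eigengenes, 1L, stats::cor, y = trait)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  data.frame(module = rownames(eigengenes), r = unname(r), p = unname(p),
             stringsAsFactors = FALSE)
}

align_trait <- function(trait, sample_ids) {
  if (is.factor(trait)) trait <- as.character(trait)
  if (is.character(trait)) trait <- as.numeric(trait == "B")
  trait <- as.numeric(trait)
  if (!is.null(names(trait))) {
    miss <- setdiff(sample_ids, names(trait))
    if (length(miss)) stop("trait missing sample(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    trait <- trait[sample_ids]
  }
  stopifnot(length(trait) == length(sample_ids), !anyNA(trait))
  trait
}

#' Module membership and gene significance
#'
#' `MM(g)` is the Pearson correlation of gene `g` with its own module's
#' eigengene (missing for grey genes); `GS(g)` is the absolute Pearson
#' correlation of the gene with the trait.
#'
#' @param expr Genes x samples matrix.
#' @param eigengenes Modules x samples matrix.
#' @param labels Module labels per gene.
#' @param trait Binary trait as in [module_trait_correlation()].
#' @return Data.frame with columns `gene`, `module`, `MM`, `GS`.
#' @export
compute_mm_gs <- function(expr, eigengenes, labels, trait) {
  trait <- align_trait(trait, colnames(expr))
  genes <- intersect(rownames(expr), names(labels))
  mm <- rep(NA_real_, length(genes))
  gs <- numeric(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    m <- labels[[g]]
    x <- expr[g, ]
    if (m != "grey" && m %in% rownames(eigengenes))
      mm[i] <- stats::cor(x, eigengenes[m, ])
    gs[i] <- abs(stats::cor(x, trait))
  }
  data.frame(gene = genes, module = unname(labels[genes]), MM = mm, GS = gs,
             stringsAsFactors = FALSE)
}

#' Merge modules with highly correlated eigengenes
#'
#' Optional post-processing: repeatedly merges the module pair whose
#' eigengenes correlate most strongly, while the maximum correlation is at
#' least `merge_cor`.  Merged modules keep the larger member's name.
#'
#' @param expr Genes x samples matrix.
#' @param labels Module labels.
#' @param merge_cor Correlation threshold (default 0.75).
#' @return Updated label vector.
#' @export
merge_close_modules <- function(expr, labels, merge_cor = 0.75) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    eg <- module_eigengenes(expr, labels)
    cc <- stats::cor(t(eg))
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (cc[mx[1L], mx[2L]] < merge_cor) break
    a <- rownames(cc)[mx[1L]]; b <- rownames(cc)[mx[2L]]
    keep <- if (sum(labels == a) >= sum(labels == b)) a else b
    drop <- setdiff(c(a, b), keep)
    labels[labels == drop] <- keep
    is_log("merge_close_modules: merged '%s' into '%s'", drop, keep)
  }
  labels
}
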
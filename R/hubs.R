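# Hub-gene screening by module membership / gene significance inside the
# cluster-associated modules, and hub ranking of a user-supplied
# interaction network by degree or maximal clique centrality (MCC).

#' Select trait-associated modules
#'
#' Keeps modules with `|r| >= r_floor` and `p <= p_ceiling` against the
#' clusterB trait and tags each with the sign of its correlation: `B+`
#' (higher in clusterB) or `B-` (lower in clusterB).
#'
#' @param module_trait Data.frame from [module_trait_correlation()].
#' @param r_floor Minimum absolute correlation (default 0.5).
#' @param p_ceiling Maximum p-value (default 0.05).
#' @return Data.frame with columns `module`, `r`, `p`, `sign`
#'   (`"B+"`/`"B-"`); zero rows (with a warning) if nothing qualifies.
#' @export
select_modules <- function(module_trait, r_floor = 0.5, p_ceiling = 0.05) {
  stopifnot(nrow(module_trait) >= 1L)
  keep <- abs(module_trait$r) >= r_floor & module_trait$p <= p_ceiling
  out <- module_trait[keep, , drop = FALSE]
  out$sign <- ifelse(out$r > 0, "B+", "B-")
  if (nrow(out) == 0L) warning("no module passed the selection rule")
  rownames(out) <- NULL
  out
}

#' Screen hub genes by MM and GS
#'
#' A gene is a hub when it lies in a selected module and satisfies
#' `MM > mm_thr` and `GS > gs_thr` (both strict).  Each hub carries its
#' module's trait sign for the immune-score construction.
#'
#' @param mm_gs Data.frame from [compute_mm_gs()].
#' @param selected Data.frame from [select_modules()].
#' @param mm_thr,gs_thr Strict thresholds in (0, 1); defaults 0.8 and 0.5.
#' @return A data.frame of class `"hub_gene_set"` with columns `gene`,
#'   `module`, `MM`, `GS`, `sign`.
#' @export
screen_hub_genes <- function(mm_gs, selected, mm_thr = 0.8, gs_thr = 0.5) {
  stopifnot(mm_thr > 0, mm_thr < 1, gs_thr > 0, gs_thr < 1)
  keep <- mm_gs$module %in% selected$module &
    !is.na(mm_gs$MM) & mm_gs$MM > mm_thr & mm_gs$GS > gs_thr
  out <- mm_gs[keep, , drop = FALSE]
  out$sign <- selected$sign[match(out$module, selected$module)]
  rownames(out) <- NULL
  for (m in unique(out$module))
    is_log("screen_hub_genes: %d hub gene(s) in module %s",
           sum(out$module == m), m)
  class(out) <- c("hub_gene_set", "data.frame")
  out
}

#' Degree ranking of an interaction network
#'
#' Undirected degree per node, sorted decreasing with ties broken by node
#' id.  Duplicate edges were already collapsed by [read_edge_list()].
#'
#' @param edges Edge-list data.frame (`from`, `to`).
#' @return Data.frame with columns `node`, `score`, sorted.
#' @export
degree_ranking <- function(edges) {
  if (nrow(edges) == 0L)
    return(data.frame(node = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  deg <- table(c(edges$from, edges$to))
  out <- data.frame(node = names(deg), score = as.numeric(deg),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$node), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Maximal clique centrality (MCC) ranking
#'
#' `MCC(v)` sums `(|C| - 1)!` over the maximal cliques `C` (size >= 2)
#' containing `v`; a node whose incident edges are all maximal cliques
#' therefore scores its degree, and an isolated node scores 0.  Maximal
#' cliques are enumerated exactly (Bron-Kerbosch with pivoting), so the
#' graph size is capped.
#'
#' @param edges Edge-list data.frame (`from`, `to`).
#' @param node_cap Maximum node count for exact enumeration (default 2000).
#' @return Data.frame with columns `node`, `score`, sorted decreasing with
#'   ties broken by node id.
#' @export
mcc_ranking <- function(edges, node_cap = 2000L) {
  if (nrow(edges) == 0L)
    return(data.frame(node = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE)
  if (igraph::vcount(g) > node_cap)
    stop("graph exceeds ", node_cap,
         " nodes; use degree_ranking() for large networks")
  cliques <- igraph::max_cliques(g, min = 2L)
  score <- stats::setNames(numeric(igraph::vcount(g)),
                           igraph::V(g)$name)
  for (cl in cliques) {
    w <- factorial(length(cl) - 1L)
    nm <- igraph::V(g)$name[as.integer(cl)]
    score[nm] <- score[nm] + w
  }
  out <- data.frame(node = names(score), score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
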
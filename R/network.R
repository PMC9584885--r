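# Protein co-abundance network: high-variance selection, positive-correlation
# edges, k-core filtering, modularity clustering, module expansion, and
# module-by-group abundance summaries. Graph primitives come from igraph.

#' Build a positive-correlation protein network
#'
#' Selects the `n_top_sd` features with the highest standard deviation (ties
#' broken by feature id), computes pairwise Pearson correlations over
#' complete pairs, and keeps edges with `r >= r_edge` (negative correlations
#' are never edges).
#'
#' @param x an [omics_matrix()].
#' @param n_top_sd number of high-SD features to keep (default 1047).
#' @param r_edge edge threshold in (0, 1) (default 0.6).
#' @return A `correlation_graph`: list with `graph` (igraph), `edges`
#'   (data.frame `source, target, r`), `nodes`, `modules` (NULL until
#'   [network_modules()]), `params`.
#' @export
build_network <- function(x, n_top_sd = 1047, r_edge = 0.6) {
  if (r_edge <= 0 || r_edge >= 1) stopf("r_edge must be in (0, 1)")
  vals <- x$values
  if (n_top_sd > nrow(vals)) stopf("n_top_sd exceeds feature count")
  sds <- apply(vals, 1, stats::sd, na.rm = TRUE)
  keep <- rownames(vals)[order(-sds, rownames(vals))][seq_len(n_top_sd)]
  cm <- stats::cor(t(vals[keep, , drop = FALSE]), use = "pairwise.complete.obs")
  cm[lower.tri(cm, diag = TRUE)] <- NA
  idx <- which(cm >= r_edge, arr.ind = TRUE)
  edges <- data.frame(source = keep[idx[, 1L]], target = keep[idx[, 2L]],
                      r = cm[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = keep))
  structure(list(graph = g, edges = edges, nodes = keep, modules = NULL,
                 params = list(n_top_sd = n_top_sd, r_edge = r_edge)),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("correlation_graph: %d nodes, %d edges%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (is.null(x$modules)) "" else
                sprintf(", %d modules", length(unique(x$modules)))))
  invisible(x)
}

#' k-core filter
#'
#' Iteratively removes nodes of degree below k until the fixed point; the
#' result (possibly empty) has every node at degree >= k, which is asserted.
#'
#' @param net a [build_network()] result.
#' @param k core order (default 3).
#' @return the filtered `correlation_graph`.
#' @export
kcore <- function(net, k = 3) {
  if (k < 1) stopf("k must be at least 1")
  g <- net$graph
  core <- igraph::coreness(g)
  g2 <- igraph::induced_subgraph(g, which(core >= k))
  stopifnot(igraph::vcount(g2) == 0 || min(igraph::degree(g2)) >= k)
  nodes <- igraph::V(g2)$name
  edges <- net$edges[net$edges$source %in% nodes & net$edges$target %in% nodes, ]
  structure(list(graph = g2, edges = edges, nodes = nodes, modules = NULL,
                 params = c(net$params, list(kcore_k = k))),
            class = "correlation_graph")
}

#' Modularity clustering of network nodes
#'
#' Louvain modularity optimization with a resolution parameter, weighted by
#' edge correlation; deterministic under the seed with fixed node ordering.
#'
#' @param net a `correlation_graph` (non-empty).
#' @param resolution modularity resolution (default 0.8).
#' @param seed RNG seed.
#' @return the graph with `modules`: named integer labels per node.
#' @export
network_modules <- function(net, resolution = 0.8, seed = 1L) {
  if (igraph::vcount(net$graph) == 0) stopf("empty graph")
  cl <- with_seed(seed, {
    igraph::cluster_louvain(net$graph, weights = igraph::E(net$graph)$r,
                            resolution = resolution)
  })
  labels <- setNames(igraph::membership(cl), igraph::V(net$graph)$name)
  net$modules <- labels
  net$params <- c(net$params, list(resolution = resolution, seed = seed))
  net
}

#' Expand a module by correlation to the full feature space
#'
#' Adds every feature of the full matrix whose Pearson correlation to any
#' module member is strictly above `r_min`.
#'
#' @param module_nodes character vector of module member ids (non-empty).
#' @param full_matrix an [omics_matrix()] over the full feature space.
#' @param r_min expansion threshold (strictly greater than; default 0.7).
#' @return character vector: module members plus recruited features.
#' @export
expand_module <- function(module_nodes, full_matrix, r_min = 0.7) {
  if (!length(module_nodes)) stopf("empty module")
  vals <- full_matrix$values
  members <- intersect(module_nodes, rownames(vals))
  if (!length(members)) stopf("module has no overlap with matrix")
  cm <- stats::cor(t(vals), t(vals[members, , drop = FALSE]),
                   use = "pairwise.complete.obs")
  maxr <- apply(cm, 1, max, na.rm = TRUE)
  recruited <- rownames(vals)[maxr > r_min]
  union(module_nodes, recruited)
}

#' Module-by-group mean abundance table
#'
#' @param x an [omics_matrix()].
#' @param modules named module labels per feature (as from
#'   [network_modules()]).
#' @param group_labels group label per sample.
#' @return matrix modules x groups of mean log2 abundance (missing-aware).
#' @export
module_group_means <- function(x, modules, group_labels) {
  stopifnot(length(group_labels) == ncol(x$values))
  mods <- sort(unique(modules))
  groups <- sort(unique(as.character(group_labels)))
  out <- matrix(NA_real_, length(mods), length(groups),
                dimnames = list(paste0("N", mods), groups))
  for (mi in seq_along(mods)) {
    feats <- intersect(names(modules)[modules == mods[mi]], rownames(x$values))
    if (!length(feats)) stopf("module %s has no features in the matrix", mods[mi])
    sub <- x$values[feats, , drop = FALSE]
    for (gi in seq_along(groups)) {
      out[mi, gi] <- mean(sub[, group_labels == groups[gi], drop = FALSE],
                          na.rm = TRUE)
    }
  }
  out
}
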
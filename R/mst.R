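#' Maximum-weight spanning tree (Kruskal)
#'
#' Runs Kruskal's algorithm on the positive-weight edges, processing edges
#' by ascending reciprocal weight 1/w (equivalently descending weight) with
#' union-find cycle rejection, so the returned tree keeps the strongest
#' connections: it maximizes total edge weight among all spanning trees.
#' Ties are broken deterministically by lexicographic (-weight, i, j)
#' order; when equal-weight edges are present the tree need not be unique
#' and a message is emitted.
#'
#' @param conn a [connectivity_matrix] whose positive-weight subgraph is
#'   connected.
#' @return An object of class `spanning_tree`: list with `n_nodes`, `edges`
#'   (data.frame `i`, `j`, `weight`, node indices in atlas order) and
#'   `roi_labels`.
#' @export
maximum_spanning_tree <- function(conn) {
  w <- as.matrix(conn)
  n <- nrow(w)
  if (n < 2L) stop("at least 2 nodes are required")
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) < n - 1L)
    stop("positive-weight subgraph cannot span ", n, " nodes")
  comp <- igraph::components(.conn_graph(conn))
  if (comp$no > 1L) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop("positive-weight subgraph is disconnected (", comp$no,
         " components of sizes ", sizes, ")")
  }
  ew <- w[idx]
  ord <- order(-ew, idx[, 1L], idx[, 2L])
  ei <- idx[ord, 1L]; ej <- idx[ord, 2L]; ew <- ew[ord]
  if (anyDuplicated(ew))
    message("equal-weight edges present; maximum spanning tree may not be unique")
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- integer(n - 1L)
  taken <- 0L
  for (e in seq_along(ew)) {
    ra <- find(ei[e]); rb <- find(ej[e])
    if (ra != rb) {
      parent[ra] <- rb
      taken <- taken + 1L
      keep[taken] <- e
      if (taken == n - 1L) break
    }
  }
  stopifnot(taken == n - 1L)
  edges <- data.frame(i = ei[keep], j = ej[keep], weight = ew[keep])
  tree <- structure(list(n_nodes = n, edges = edges,
                         roi_labels = rownames(w)),
                    class = "spanning_tree")
  .validate_tree(tree)
  tree
}

.validate_tree <- function(tree) {
  stopifnot(nrow(tree$edges) == tree$n_nodes - 1L,
            all(tree$edges$weight > 0))
  g <- .tree_graph(tree)
  stopifnot(igraph::is_connected(g))  # n-1 edges + connected => acyclic
  invisible(tree)
}

# unweighted igraph view of the tree (all tree metrics are hop-based)
.tree_graph <- function(tree) {
  igraph::graph_from_edgelist(as.matrix(tree$edges[, c("i", "j")]),
                              directed = FALSE) |>
    igraph::add_vertices(nv = tree$n_nodes - max(c(0L, tree$edges$i, tree$edges$j)))
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("Spanning tree: %d nodes, %d edges, total weight %.4f\n",
              x$n_nodes, nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Local tree descriptors: degree, betweenness, eccentricity
#'
#' Raw and normalized per-node descriptors of a spanning tree. Degree is
#' the edge count per node (hub metric). Betweenness is the fraction of
#' all (n-1)(n-2)/2 unordered node pairs whose unique tree path passes
#' through the node (endpoints excluded), so it lies in \[0, 1\] and a
#' star centre attains exactly 1. Eccentricity is the maximum hop distance
#' to any other node. Degree and betweenness are additionally divided by
#' their within-tree maximum; eccentricity by (n - 1), the longest
#' possible tree path.
#'
#' @param tree a `spanning_tree`.
#' @return An object of class `mst_local_metrics`: list of named vectors
#'   `degree`, `degree_norm`, `betweenness`, `betweenness_norm`,
#'   `eccentricity`, `eccentricity_norm`.
#' @export
mst_local_metrics <- function(tree) {
  g <- .tree_graph(tree)
  n <- tree$n_nodes
  labels <- tree$roi_labels
  k <- as.numeric(igraph::degree(g))
  bc <- as.numeric(igraph::betweenness(g, directed = FALSE, weights = NA,
                                       normalized = n > 2L))
  ecc <- as.numeric(igraph::eccentricity(g))
  norm_max <- function(x) if (max(x) > 0) x / max(x) else x
  nm <- function(x) stats::setNames(x, labels)
  structure(list(
    degree = nm(k), degree_norm = nm(norm_max(k)),
    betweenness = nm(bc), betweenness_norm = nm(norm_max(bc)),
    eccentricity = nm(ecc), eccentricity_norm = nm(ecc / (n - 1))
  ), class = "mst_local_metrics")
}

#' Global tree descriptors
#'
#' Six whole-tree descriptors: diameter `d` (maximum eccentricity) and
#' radius `r` (minimum eccentricity), both on the hop scale divided by
#' (n - 1); leaf fraction \eqn{L_f = N_{leaf} / (n - 1)}; tree hierarchy
#' \eqn{T_h = N_{leaf} / (2 (n - 1) BC_{max})} with \eqn{BC_{max}} the
#' maximum pair-fraction betweenness (an optimal tree balances diameter
#' reduction against hub overload, with \eqn{T_h} approaching 0.5); degree
#' divergence \eqn{\kappa = \langle k^2 \rangle / \langle k \rangle} over
#' raw degrees; and degree correlation `r_deg`, the Pearson correlation of
#' endpoint degrees over both orientations of every edge (assortativity;
#' -1 for a star).
#'
#' @param tree a `spanning_tree`.
#' @param local matching [mst_local_metrics()]; recomputed when omitted.
#' @return An object of class `mst_global_metrics`: list with `diameter`,
#'   `radius`, `leaf_fraction`, `tree_hierarchy`, `kappa`,
#'   `degree_correlation`, and `n_leaf`.
#' @export
mst_global_metrics <- function(tree, local = NULL) {
  if (is.null(local)) local <- mst_local_metrics(tree)
  n <- tree$n_nodes
  k <- local$degree
  n_leaf <- sum(k == 1)
  bc_max <- max(local$betweenness)
  r_deg <- NA_real_
  if (n >= 3L) {
    x <- c(k[tree$edges$i], k[tree$edges$j])
    y <- c(k[tree$edges$j], k[tree$edges$i])
    if (stats::sd(x) > 0) r_deg <- stats::cor(x, y)
  }
  structure(list(
    diameter = max(local$eccentricity) / (n - 1),
    radius = min(local$eccentricity) / (n - 1),
    leaf_fraction = n_leaf / (n - 1),
    tree_hierarchy = if (bc_max > 0) n_leaf / (2 * (n - 1) * bc_max) else NA_real_,
    kappa = mean(k^2) / mean(k),
    degree_correlation = r_deg,
    n_leaf = n_leaf
  ), class = "mst_global_metrics")
}

#' Serialize a spanning tree as an edge-list TSV
#'
#' Columns `node_i`, `node_j`, `weight`, with ROI names.
#'
#' @param tree a `spanning_tree`.
#' @param path file path.
#' @export
write_spanning_tree <- function(tree, path) {
  df <- data.frame(node_i = tree$roi_labels[tree$edges$i],
                   node_j = tree$roi_labels[tree$edges$j],
                   weight = tree$edges$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
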
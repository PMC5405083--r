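#' Weighted clustering coefficient (geometric-mean / Onnela form)
#'
#' Per-node weighted clustering on max-normalized weights: with
#' \eqn{\hat w = w / \max(w)}, the triangle intensity around node i is
#' \eqn{t_i = \frac{1}{2}\sum_{j,k} (\hat w_{ij}\hat w_{jk}\hat w_{ki})^{1/3}}
#' and \eqn{C_i = 2 t_i / (k_i (k_i - 1))} with \eqn{k_i} the binary degree.
#' Nodes with fewer than two neighbours get \eqn{C_i = 0}. The mean over
#' nodes is the global coefficient \eqn{C_w}, a segregation measure.
#'
#' @param conn a [connectivity_matrix].
#' @return List with `per_node` (named C_i vector) and `mean` (C_w).
#' @export
weighted_clustering <- function(conn) {
  w <- as.matrix(conn)
  n <- nrow(w)
  mx <- max(w)
  per_node <- stats::setNames(numeric(n), rownames(w))
  if (mx > 0) {
    wc <- (w / mx)^(1 / 3)
    t_i <- diag(wc %*% wc %*% wc) / 2
    k <- rowSums(w > 0)
    ok <- k >= 2
    per_node[ok] <- 2 * t_i[ok] / (k[ok] * (k[ok] - 1))
  }
  list(per_node = per_node, mean = mean(per_node))
}

#' Shortest weighted path lengths
#'
#' Edge length is the reciprocal weight 1/w (strong correlations are short
#' hops); distances are Dijkstra shortest totals over all paths. Pairs in
#' different components get `Inf` and the result carries a
#' `disconnected` attribute.
#'
#' @param conn a [connectivity_matrix].
#' @return Numeric distance matrix with attribute `disconnected`.
#' @export
shortest_path_lengths <- function(conn) {
  g <- .conn_graph(conn)
  if (igraph::ecount(g) == 0L) {
    d <- matrix(Inf, nrow(conn), ncol(conn), dimnames = dimnames(conn))
    diag(d) <- 0
  } else {
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                           algorithm = "dijkstra")
  }
  attr(d, "disconnected") <- any(!is.finite(d[upper.tri(d)]))
  d
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered node pairs,
#' \eqn{L_w = \frac{1}{n}\sum_i \sum_{j \ne i} d_{ij} / (n - 1)}; the
#' integration measure of the weighted graph.
#'
#' @param dists distance matrix from [shortest_path_lengths()].
#' @param fallback `"error"` (default) raises on infinite distances;
#'   `"harmonic"` returns the harmonic mean of distances instead
#'   (unreachable pairs contribute zero inverse distance), clearly labelled
#'   via the `"method"` attribute.
#' @return L_w (scalar, with attribute `method`).
#' @export
characteristic_path_length <- function(dists, fallback = c("error", "harmonic")) {
  fallback <- match.arg(fallback)
  off <- dists[row(dists) != col(dists)]
  if (any(!is.finite(off))) {
    if (fallback == "error")
      stop("graph is disconnected: infinite distances (set fallback = \"harmonic\" to average reciprocals)")
    l <- 1 / mean(1 / off)  # 1/Inf == 0
    return(structure(l, method = "harmonic"))
  }
  structure(mean(off), method = "arithmetic")
}

#' Connectivity cost
#'
#' Mean off-diagonal edge weight,
#' \eqn{conn = \frac{1}{n(n-1)} \sum_{i \ne j} w_{ij}} (absent edges count
#' as 0); the average wiring cost of the network.
#'
#' @param conn a [connectivity_matrix].
#' @return Scalar cost.
#' @export
connectivity_cost <- function(conn) {
  w <- as.matrix(conn)
  n <- nrow(w)
  if (n < 2L) stop("at least 2 nodes are required")
  sum(w) / (n * (n - 1))
}

#' Edge- and weight-preserving null ensemble
#'
#' Generates random surrogate networks by Maslov-Sneppen double-edge
#' swaps: two edges (a,b), (c,d) are rewired to (a,d), (c,b) (or (a,c),
#' (b,d)) whenever this creates neither self-loops nor duplicate edges.
#' Weights travel with their edges, so every null preserves the degree
#' sequence exactly and the multiset of edge weights exactly while
#' randomizing topology.
#'
#' @param conn a [connectivity_matrix].
#' @param n_null ensemble size (default 100).
#' @param iterations_per_edge swap attempts per edge per null (default 10).
#' @param seed optional RNG seed for reproducibility.
#' @return List of `n_null` [connectivity_matrix] objects.
#' @export
null_ensemble <- function(conn, n_null = 100, iterations_per_edge = 10,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- as.matrix(conn)
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(idx)
  if (m == max_edge_count(n)) {
    warning("complete graph cannot be rewired; nulls equal the input")
    return(replicate(n_null, conn, simplify = FALSE))
  }
  if (m < 2L) stop("at least two rewirable edges are required")
  attempts <- ceiling(iterations_per_edge * m)
  nulls <- vector("list", n_null)
  for (b in seq_len(n_null)) {
    ei <- idx[, 1L]; ej <- idx[, 2L]
    ew <- w[idx]
    adj <- w > 0
    swapped <- 0L
    for (it in seq_len(attempts)) {
      pick <- sample.int(m, 2L)
      a <- ei[pick[1L]]; bb <- ej[pick[1L]]
      cc <- ei[pick[2L]]; d <- ej[pick[2L]]
      if (stats::runif(1) < 0.5) { tmp <- cc; cc <- d; d <- tmp }
      # proposed new edges: (a, d) and (cc, bb)
      if (length(unique(c(a, bb, cc, d))) < 4L) next
      if (adj[a, d] || adj[cc, bb]) next
      adj[a, bb] <- adj[bb, a] <- FALSE
      adj[cc, d] <- adj[d, cc] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[cc, bb] <- adj[bb, cc] <- TRUE
      ei[pick[1L]] <- min(a, d); ej[pick[1L]] <- max(a, d)
      ei[pick[2L]] <- min(cc, bb); ej[pick[2L]] <- max(cc, bb)
      swapped <- swapped + 1L
    }
    if (swapped == 0L)
      warning("no successful rewiring swaps; null ", b, " equals the input")
    wn <- matrix(0, n, n, dimnames = dimnames(w))
    wn[cbind(ei, ej)] <- ew
    wn <- wn + t(wn)
    nulls[[b]] <- connectivity_matrix(wn)
  }
  nulls
}

#' Small-worldness against a null ensemble
#'
#' Scores a weighted network against random edge- and weight-preserving
#' surrogates: \eqn{\gamma^w = C_w / C_w^{rand}},
#' \eqn{\lambda^w = L_w / L_w^{rand}} (ensemble means), and
#' \eqn{\sigma^w = \gamma^w / \lambda^w}. A small-world network combines
#' higher segregation than random (\eqn{\gamma^w \gg 1}) with comparable
#' integration (\eqn{\lambda^w \approx 1}) and so attains
#' \eqn{\sigma^w > 1}.
#'
#' @param conn a [connectivity_matrix]; must be connected.
#' @param n_null ensemble size (default 100); ignored when `ensemble` is
#'   supplied.
#' @param iterations_per_edge swap attempts per edge per null.
#' @param seed optional RNG seed.
#' @param ensemble optional pre-built list of null matrices.
#' @param fallback path-length behaviour for disconnected graphs, passed to
#'   [characteristic_path_length()].
#' @return An object of class `small_world_result`: list with `c_w`, `l_w`,
#'   `c_w_rand`, `l_w_rand`, `gamma`, `lambda`, `sigma`, `conn`, `n_null`,
#'   and `per_node_clustering`.
#' @export
small_worldness <- function(conn, n_null = 100, iterations_per_edge = 10,
                            seed = NULL, ensemble = NULL,
                            fallback = c("error", "harmonic")) {
  fallback <- match.arg(fallback)
  if (is.null(ensemble))
    ensemble <- null_ensemble(conn, n_null = n_null,
                              iterations_per_edge = iterations_per_edge,
                              seed = seed)
  if (!length(ensemble)) stop("null ensemble must be nonempty")
  cl <- weighted_clustering(conn)
  l_w <- as.numeric(characteristic_path_length(shortest_path_lengths(conn),
                                               fallback = fallback))
  null_c <- vapply(ensemble, function(x) weighted_clustering(x)$mean, 0)
  null_l <- vapply(ensemble, function(x)
    as.numeric(characteristic_path_length(shortest_path_lengths(x),
                                          fallback = fallback)), 0)
  c_rand <- mean(null_c)
  l_rand <- mean(null_l)
  if (c_rand == 0 || l_rand == 0) stop("null ensemble mean is zero")
  gamma <- cl$mean / c_rand
  lam <- l_w / l_rand
  structure(list(
    c_w = cl$mean, l_w = l_w, c_w_rand = c_rand, l_w_rand = l_rand,
    gamma = gamma, lambda = lam, sigma = gamma / lam,
    conn = connectivity_cost(conn), n_null = length(ensemble),
    per_node_clustering = cl$per_node
  ), class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf(
    "Small-world panel (%d nulls):\n  C_w = %.4f  L_w = %.4f  conn = %.4f\n  gamma = %.4f  lambda = %.4f  sigma = %.4f\n",
    x$n_null, x$c_w, x$l_w, x$conn, x$gamma, x$lambda, x$sigma))
  invisible(x)
}
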
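# Brute-force oracles, deliberately independent of the package internals
# (no igraph): triple loops, exhaustive path / spanning-tree enumeration,
# hand-walked tree paths. Only usable at toy sizes.

# random symmetric weight matrix in [0,1], zero diagonal, given edge density
random_connectivity <- function(n, density = 0.7, wmin = 0.05, wmax = 1) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (stats::runif(1) < density)
        w[i, j] <- w[j, i] <- stats::runif(1, wmin, wmax)
    }
  }
  w
}

# connected check by label propagation (no igraph)
oracle_is_connected <- function(w) {
  n <- nrow(w)
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(w[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# draws until the random graph is connected
random_connected_connectivity <- function(n, density = 0.7) {
  repeat {
    w <- random_connectivity(n, density)
    if (oracle_is_connected(w)) return(w)
  }
}

# weighted clustering coefficient by explicit triple loop (max-normalized)
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  wh <- if (mx > 0) w / mx else w
  k <- rowSums(w > 0)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- 0
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        t_i <- t_i + (wh[i, j] * wh[j, l] * wh[l, i])^(1 / 3)
      }
    }
    t_i <- t_i / 2
    if (k[i] >= 2) ci[i] <- 2 * t_i / (k[i] * (k[i] - 1))
  }
  ci
}

# all-pairs shortest path lengths (edge length 1/w) by exhaustive
# enumeration of simple paths
oracle_shortest_paths <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  recurse <- function(v, target, visited, acc) {
    if (v == target) {
      best[visited[1L], target] <<- min(best[visited[1L], target], acc)
      return(invisible())
    }
    for (u in which(w[v, ] > 0)) {
      if (!(u %in% visited)) recurse(u, target, c(visited, u), acc + len[v, u])
    }
  }
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s != t) recurse(s, t, s, 0)
    }
  }
  pmin(best, t(best))
}

# maximum spanning-tree weight by enumerating all (n-1)-edge subsets
oracle_max_tree_weight <- function(w) {
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(idx)
  stopifnot(m >= n - 1)
  best <- -Inf
  sets <- utils::combn(m, n - 1)
  for (c_i in seq_len(ncol(sets))) {
    sel <- sets[, c_i]
    # spanning + acyclic check by component merging
    comp <- seq_len(n)
    ok <- TRUE
    for (e in sel) {
      a <- comp[idx[e, 1L]]
      b <- comp[idx[e, 2L]]
      if (a == b) { ok <- FALSE; break }
      comp[comp == b] <- a
    }
    if (ok && length(unique(comp)) == 1L)
      best <- max(best, sum(w[idx[sel, , drop = FALSE]]))
  }
  best
}

# random tree by sequential random attachment, random weights
random_tree_matrix <- function(n, wmin = 0.1, wmax = 1) {
  w <- matrix(0, n, n)
  for (v in seq(2L, n)) {
    u <- sample.int(v - 1L, 1L)
    w[u, v] <- w[v, u] <- stats::runif(1, wmin, wmax)
  }
  w
}

# unique tree path between two nodes, by DFS on the adjacency matrix
oracle_tree_path <- function(w, from, to) {
  n <- nrow(w)
  parent <- rep(NA_integer_, n)
  stack <- from
  seen <- rep(FALSE, n)
  seen[from] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == to) break
    for (u in which(w[v, ] > 0)) {
      if (!seen[u]) {
        seen[u] <- TRUE
        parent[u] <- v
        stack <- c(stack, u)
      }
    }
  }
  path <- to
  while (path[1L] != from) path <- c(parent[path[1L]], path)
  path
}

# tree betweenness: fraction of unordered pairs whose path passes through
# each node (endpoints excluded)
oracle_tree_bc <- function(w) {
  n <- nrow(w)
  counts <- numeric(n)
  hops <- matrix(0L, n, n)
  for (k in seq_len(n - 1L)) {
    for (l in seq(k + 1L, n)) {
      path <- oracle_tree_path(w, k, l)
      hops[k, l] <- hops[l, k] <- length(path) - 1L
      interior <- setdiff(path, c(k, l))
      counts[interior] <- counts[interior] + 1
    }
  }
  list(fraction = counts / ((n - 1) * (n - 2) / 2),
       pair_counts = counts, hops = hops)
}

# helper to wrap a plain matrix into the package container
as_conn <- function(w) connectivity_matrix(w, roi_labels = paste0("R", seq_len(nrow(w))))

# spanning tree on explicit edges
tree_from_edges <- function(n, edges_ij, weights = rep(0.5, nrow(edges_ij))) {
  w <- matrix(0, n, n)
  for (e in seq_len(nrow(edges_ij))) {
    w[edges_ij[e, 1L], edges_ij[e, 2L]] <- weights[e]
    w[edges_ij[e, 2L], edges_ij[e, 1L]] <- weights[e]
  }
  maximum_spanning_tree(as_conn(w))
}

star_conn <- function(n, weight = 0.5) {
  w <- matrix(0, n, n)
  w[1L, 2:n] <- w[2:n, 1L] <- weight
  as_conn(w)
}

path_conn <- function(n, weight = 0.5) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) w[i, i + 1L] <- w[i + 1L, i] <- weight
  as_conn(w)
}

# ring lattice where every node links to its k nearest neighbours, uniform
# weights: the canonical high-clustering, long-path topology
ring_lattice_conn <- function(n, k = 4, weight = 0.6) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in seq_len(k / 2)) {
      j <- ((i - 1 + d) %% n) + 1
      w[i, j] <- w[j, i] <- weight
    }
  }
  as_conn(w)
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
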
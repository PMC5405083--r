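#' Weighted connectivity matrix
#'
#' Symmetric nonnegative weighted adjacency over ROIs: entry (i, j) is the
#' (nonnegative) Pearson correlation between regions i and j, the diagonal
#' is exactly 0 so the matrix doubles as an adjacency matrix, and a zero
#' entry means "no edge".
#'
#' @param weights symmetric numeric matrix with zero diagonal and entries
#'   in \[0, 1\].
#' @param roi_labels character labels for the rows/columns.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, roi_labels = rownames(weights)) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights)) stop("weights must be square")
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(n))
  if (length(roi_labels) != n) stop("roi_labels must match matrix dimension")
  if (anyNA(weights)) stop("weights must not contain missing values")
  if (max(abs(weights - t(weights))) > 1e-10) stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) stop("diagonal must be exactly 0")
  if (any(weights < 0) || any(weights > 1)) stop("weights must lie in [0, 1]")
  dimnames(weights) <- list(roi_labels, roi_labels)
  structure(weights, class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Connectivity matrix: %d ROIs, %d of %d possible edges, mean weight %.4f\n",
              n, sum(x[upper.tri(x)] > 0), max_edge_count(n),
              mean(x[upper.tri(x)])))
  invisible(x)
}

#' Functional connectivity from ROI time-series
#'
#' Pearson correlation between every pair of ROI signals; negative
#' correlations are discarded (set to exact 0, i.e. no edge) and the
#' diagonal is stored as 0.
#'
#' @param ts a [roi_timeseries] (or plain frames-by-ROIs matrix).
#' @return A [connectivity_matrix].
#' @export
build_connectivity <- function(ts) {
  m <- as.matrix(ts)
  if (nrow(m) < 3L) stop("at least 3 frames are required")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance ROI signal: ", paste(bad, collapse = ", "))
  }
  w <- stats::cor(m)
  w[w < 0] <- 0
  diag(w) <- 0
  connectivity_matrix(w, roi_labels = colnames(m))
}

#' Read / write a connectivity matrix TSV
#'
#' Square table with an ROI-name header row and index column.
#'
#' @param conn a [connectivity_matrix] (for writing).
#' @param path file path.
#' @export
write_connectivity <- function(conn, path) {
  df <- data.frame(roi = rownames(conn), as.matrix(conn), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  labels <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- labels
  connectivity_matrix(m, roi_labels = labels)
}

# igraph view of a connectivity matrix (edge weights attached)
.conn_graph <- function(conn) {
  igraph::graph_from_adjacency_matrix(as.matrix(conn), mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
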
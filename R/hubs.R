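#' Hub fractions from per-subject argmax
#'
#' For each subject, finds the ROI(s) attaining the maximum of a nodal
#' metric (degree or betweenness of the subject's spanning tree); the hub
#' profile of a population is the per-ROI fraction of subjects whose
#' maximum occurs there. Ties credit every tied ROI, so fractions can sum
#' to slightly more than 1; with continuous weights ties are practically
#' impossible and fractions sum to exactly 1. The result is invariant to
#' any monotone rescaling of the metric.
#'
#' @param metric_table subjects-by-ROI numeric matrix (ROI names as column
#'   names, subject ids as row names).
#' @param population optional subject subset: row indices, ids, or a
#'   logical vector. Default: all subjects.
#' @param tol tie tolerance (values within `tol` of the row maximum count
#'   as maximal).
#' @return An object of class `hub_profile`: named per-ROI fraction vector
#'   with attributes `n_subjects`.
#' @export
hub_fractions <- function(metric_table, population = NULL, tol = 1e-8) {
  m <- as.matrix(metric_table)
  if (!is.null(population)) m <- m[population, , drop = FALSE]
  if (nrow(m) == 0L) stop("population is empty")
  counts <- numeric(ncol(m))
  for (s in seq_len(nrow(m))) {
    v <- m[s, ]
    counts <- counts + (v >= max(v) - tol)
  }
  structure(stats::setNames(counts / nrow(m), colnames(m)),
            n_subjects = nrow(m), class = "hub_profile")
}

#' @export
print.hub_profile <- function(x, ...) {
  top <- sort(unclass(x), decreasing = TRUE)[1:min(5L, length(x))]
  cat("Hub profile over", attr(x, "n_subjects"), "subjects; top ROIs:\n")
  print(round(top, 3))
  invisible(x)
}

#' Correlate a nodal metric with median response times
#'
#' Pearson correlation, across the subjects of a population, between each
#' ROI's metric value and the subjects' median response times (MRT), with
#' two-sided p-values from the t distribution on n - 2 degrees of
#' freedom. The reported `best_roi` is the ROI with the largest positive
#' correlation (`method = "positive"`, the default) or the largest
#' absolute correlation. ROIs with constant metric values are reported as
#' missing. P-values are unadjusted; apply [fdr_bh()] across ROIs if a
#' corrected family is wanted.
#'
#' @param metric_table subjects-by-ROI numeric matrix.
#' @param mrt per-subject MRT vector aligned with the rows.
#' @param population optional subject subset (indices, ids, or logical).
#' @param method best-ROI selection rule.
#' @return An object of class `mrt_correlation`: list with per-ROI `r` and
#'   `p` vectors, `best_roi` (name), `best_r`, `best_p`, `n_subjects`.
#' @export
mrt_correlation <- function(metric_table, mrt, population = NULL,
                            method = c("positive", "absolute")) {
  method <- match.arg(method)
  m <- as.matrix(metric_table)
  stopifnot(length(mrt) == nrow(m))
  if (!is.null(population)) {
    m <- m[population, , drop = FALSE]
    mrt <- if (is.character(population)) mrt[match(rownames(m), rownames(metric_table))]
           else mrt[population]
  }
  n <- nrow(m)
  if (n < 4L) stop("population size must be at least 4")
  if (stats::sd(mrt) == 0) stop("MRT is constant")
  r <- p <- stats::setNames(rep(NA_real_, ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (stats::sd(x) == 0) next
    ct <- stats::cor.test(x, mrt, method = "pearson")
    r[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  if (all(is.na(r))) stop("all metric columns are constant")
  score <- if (method == "positive") r else abs(r)
  best <- NA_character_
  if (method == "positive" && all(score <= 0, na.rm = TRUE)) {
    message("no ROI has a positive correlation with MRT")
  } else {
    best <- names(which.max(score))
  }
  structure(list(r = r, p = p, best_roi = best,
                 best_r = if (is.na(best)) NA_real_ else r[[best]],
                 best_p = if (is.na(best)) NA_real_ else p[[best]],
                 n_subjects = n, method = method),
            class = "mrt_correlation")
}

#' @export
print.mrt_correlation <- function(x, ...) {
  cat(sprintf("Metric-MRT correlations over %d subjects; best ROI: %s (r = %.3f, p = %.4g)\n",
              x$n_subjects, x$best_roi, x$best_r, x$best_p))
  invisible(x)
}
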
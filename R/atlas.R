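#' ROI atlas
#'
#' Lightweight container pairing ROI names with the integer codes used in a
#' label volume. The label order is fixed and shared by every downstream
#' matrix (time-series columns, connectivity rows/columns, tree nodes).
#'
#' @param labels character vector of unique ROI names, in canonical order.
#' @param ids positive integer codes matching the label volume; defaults to
#'   `seq_along(labels)`.
#' @param voxel_counts optional per-ROI voxel counts.
#' @return An object of class `roi_atlas`.
#' @export
roi_atlas <- function(labels, ids = seq_along(labels), voxel_counts = NULL) {
  labels <- as.character(labels)
  ids <- as.integer(ids)
  if (anyDuplicated(labels)) stop("ROI labels must be unique")
  if (length(ids) != length(labels)) stop("ids and labels must have equal length")
  if (anyDuplicated(ids) || any(ids <= 0L)) stop("ROI ids must be unique positive integers")
  if (!is.null(voxel_counts) && length(voxel_counts) != length(labels))
    stop("voxel_counts must match labels")
  structure(
    list(labels = labels, ids = ids, voxel_counts = voxel_counts),
    class = "roi_atlas"
  )
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("ROI atlas with", length(x$labels), "regions\n")
  utils::head(data.frame(id = x$ids, name = x$labels)) |> print()
  if (length(x$labels) > 6L) cat("...\n")
  invisible(x)
}

#' @export
length.roi_atlas <- function(x) length(x$labels)

#' Cerebellar lobule atlas
#'
#' The 28-region cerebellar parcellation (left/right lobules I-IV through X
#' plus vermal subdivisions) shipped with the package as a plain id/name
#' lookup table.
#'
#' @return A [roi_atlas] with 28 regions.
#' @export
cerebellum_atlas <- function() {
  path <- system.file("extdata", "suit_lobules.tsv", package = "fcmst", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  roi_atlas(labels = tab$name, ids = tab$id)
}

#' Drop named ROIs from an atlas
#'
#' Removes regions (e.g. the tiny "Vermis Crus I" lobule, below 0.005% of
#' cerebellar volume) while preserving the relative order of the remainder.
#'
#' @param atlas a [roi_atlas].
#' @param exclusion_names character vector of label names to drop; every
#'   name must exist in the atlas.
#' @return A [roi_atlas] without the excluded regions.
#' @export
exclude_rois <- function(atlas, exclusion_names) {
  stopifnot(inherits(atlas, "roi_atlas"))
  exclusion_names <- as.character(exclusion_names)
  missing <- setdiff(exclusion_names, atlas$labels)
  if (length(missing))
    stop("unknown ROI name(s): ", paste(missing, collapse = ", "))
  keep <- !(atlas$labels %in% exclusion_names)
  roi_atlas(
    labels = atlas$labels[keep],
    ids = atlas$ids[keep],
    voxel_counts = atlas$voxel_counts[keep]
  )
}

#' Maximum number of edges in an undirected graph on n nodes
#'
#' @param n node count.
#' @return `n * (n - 1) / 2`.
#' @export
max_edge_count <- function(n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 0L)
  n * (n - 1L) / 2
}
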
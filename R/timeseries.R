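#' ROI time-series container
#'
#' A frames-by-ROIs numeric matrix with ROI labels and the sampling
#' interval (repetition time) attached.
#'
#' @param values numeric matrix, frames in rows, ROIs in columns.
#' @param roi_labels character vector naming the columns; defaults to
#'   existing column names.
#' @param sampling_interval sampling interval in seconds (default 0.72, a
#'   typical fast-TR resting-state protocol).
#' @return An object of class `roi_timeseries` (a matrix with attributes).
#' @export
roi_timeseries <- function(values, roi_labels = colnames(values),
                           sampling_interval = 0.72) {
  values <- as.matrix(values)
  if (is.null(roi_labels)) stop("roi_labels are required")
  if (length(roi_labels) != ncol(values))
    stop("column count (", ncol(values), ") must equal label count (",
         length(roi_labels), ")")
  if (anyNA(values)) stop("time-series must not contain missing values")
  if (nrow(values) < 3L) stop("at least 3 frames are required")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop("sampling_interval must be a positive number of seconds")
  colnames(values) <- as.character(roi_labels)
  structure(values, sampling_interval = sampling_interval,
            class = c("roi_timeseries", "matrix", "array"))
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time-series: %d frames x %d ROIs (TR = %gs)\n",
              nrow(x), ncol(x), attr(x, "sampling_interval")))
  invisible(x)
}

#' Average a 4D volume series over atlas-labelled voxels
#'
#' Computes, for every ROI in the atlas and every frame, the unweighted
#' mean of the voxels whose integer label equals the ROI's id. This is the
#' standard mean-signal extraction step that turns a preprocessed 4D BOLD
#' image plus an anatomical label volume into a frames-by-ROIs matrix.
#'
#' @param volume_series 4D numeric array (x, y, z, frames), or a path to a
#'   NIfTI file (requires the RNifti package).
#' @param label_volume 3D integer array on the same spatial grid, 0 =
#'   background, or a NIfTI path.
#' @param atlas a [roi_atlas]; every id must be present in `label_volume`.
#' @param sampling_interval seconds per frame for the output container.
#' @return A [roi_timeseries] in atlas order.
#' @export
extract_roi_means <- function(volume_series, label_volume, atlas,
                              sampling_interval = 0.72) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (is.character(volume_series)) volume_series <- .read_nifti_array(volume_series)
  if (is.character(label_volume)) label_volume <- .read_nifti_array(label_volume)
  dv <- dim(volume_series)
  dl <- dim(label_volume)
  if (length(dv) != 4L) stop("volume_series must be a 4D array")
  if (length(dl) != 3L) stop("label_volume must be a 3D array")
  if (!all(dv[1:3] == dl))
    stop("spatial grid mismatch: volume is ", paste(dv[1:3], collapse = "x"),
         ", labels are ", paste(dl, collapse = "x"))
  n_frames <- dv[4]
  flat <- matrix(volume_series, nrow = prod(dv[1:3]), ncol = n_frames)
  lab <- as.integer(label_volume)
  out <- matrix(NA_real_, nrow = n_frames, ncol = length(atlas$labels))
  for (k in seq_along(atlas$ids)) {
    vox <- which(lab == atlas$ids[k])
    if (!length(vox))
      stop("atlas id ", atlas$ids[k], " ('", atlas$labels[k],
           "') is absent from the label volume")
    out[, k] <- colMeans(flat[vox, , drop = FALSE])
  }
  roi_timeseries(out, roi_labels = atlas$labels,
                 sampling_interval = sampling_interval)
}

.read_nifti_array <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI files requires the RNifti package")
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Read / write ROI time-series TSV
#'
#' Plain-text interchange format: one header row of ROI names, one row per
#' frame.
#'
#' @param path file path.
#' @param ts a [roi_timeseries] (for writing).
#' @param sampling_interval seconds per frame assumed when reading.
#' @return `read_roi_timeseries` returns a [roi_timeseries];
#'   `write_roi_timeseries` returns `path` invisibly.
#' @export
read_roi_timeseries <- function(path, sampling_interval = 0.72) {
  tab <- utils::read.delim(path, check.names = FALSE)
  roi_timeseries(as.matrix(tab), roi_labels = colnames(tab),
                 sampling_interval = sampling_interval)
}

#' @rdname read_roi_timeseries
#' @export
write_roi_timeseries <- function(ts, path) {
  utils::write.table(as.matrix(ts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = colnames(ts))
  invisible(path)
}
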
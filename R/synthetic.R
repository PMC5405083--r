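#' Synthetic cohort configuration
#'
#' Declares the statistical structure of a simulated resting-state cohort:
#' modular correlation blocks between ROIs, an optional planted hub whose
#' correlations are uniformly boosted, optional per-group multipliers on
#' the within/between-module correlations (to plant group differences in
#' clustering/density), and an optional planted correlation between one
#' ROI's tree metric and median response time (MRT) in one group.
#'
#' Defaults emulate a fast-TR resting-state protocol: 27 ROIs, 1200 frames
#' at 0.72 s, four correlation modules, within/between module correlations
#' 0.3 / 0.1, hub boost +0.25.
#'
#' @param n_subjects_per_group subjects per group; scalar or named vector
#'   over `group_labels`.
#' @param n_rois number of ROIs (default 27).
#' @param n_frames frames per subject (default 1200).
#' @param sampling_interval seconds per frame (default 0.72).
#' @param modules integer vector of length `n_rois` assigning each ROI to a
#'   community; default splits the ROIs into 4 contiguous blocks.
#' @param within_module_corr,between_module_corr target correlations inside
#'   and across modules; must satisfy
#'   `0 <= between_module_corr <= within_module_corr < 1`.
#' @param hub_roi ROI index whose row/column correlations are raised by
#'   `hub_boost` (clipped below 1), or `NULL` for no planted hub.
#' @param hub_boost additive correlation increment for the hub (default 0.25).
#' @param group_effects optional named list, one entry per group, each a
#'   vector like `c(within = 1.1, between = 0.9)` multiplying the base
#'   correlations for that group.
#' @param mrt_link optional list `list(group =, roi =, rho =, metric =)`
#'   planting a population correlation `rho` between the named tree metric
#'   (`"betweenness"` or `"degree"`) at ROI `roi` and MRT in the given
#'   group; requires `|rho| < 1`.
#' @param group_labels labels drawn from `c("low", "high", "mid")`.
#' @param female_prop probability a simulated subject is female (default 0.6).
#' @param ar_coef AR(1) coefficient for temporal smoothing of the latent
#'   noise; default 0 (i.i.d. Gaussian frames).
#' @param mrt_meanlog,mrt_sdlog lognormal MRT marginal parameters on the
#'   millisecond scale (defaults `log(8000)` and 0.3).
#' @param seed RNG seed making the whole cohort reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_group, n_rois = 27, n_frames = 1200,
                          sampling_interval = 0.72, modules = NULL,
                          within_module_corr = 0.3, between_module_corr = 0.1,
                          hub_roi = NULL, hub_boost = 0.25,
                          group_effects = NULL, mrt_link = NULL,
                          group_labels = c("low", "high"),
                          female_prop = 0.6, ar_coef = 0,
                          mrt_meanlog = log(8000), mrt_sdlog = 0.3,
                          seed = 1L) {
  n_rois <- as.integer(n_rois)
  if (is.null(modules))
    modules <- sort(rep_len(seq_len(4L), n_rois))
  if (length(modules) != n_rois) stop("modules must assign every ROI")
  if (!(between_module_corr >= 0 && between_module_corr <= within_module_corr &&
        within_module_corr < 1))
    stop("need 0 <= between_module_corr <= within_module_corr < 1")
  stopifnot(all(group_labels %in% c("low", "high", "mid")),
            !anyDuplicated(group_labels))
  if (length(n_subjects_per_group) == 1L && is.null(names(n_subjects_per_group)))
    n_subjects_per_group <- stats::setNames(
      rep(as.integer(n_subjects_per_group), length(group_labels)), group_labels)
  if (!setequal(names(n_subjects_per_group), group_labels))
    stop("n_subjects_per_group names must match group_labels")
  if (!is.null(hub_roi)) {
    hub_roi <- as.integer(hub_roi)
    stopifnot(hub_roi >= 1L, hub_roi <= n_rois)
  }
  if (!is.null(group_effects) &&
      !all(names(group_effects) %in% group_labels))
    stop("group_effects names must be group labels")
  if (!is.null(mrt_link)) {
    stopifnot(is.list(mrt_link),
              all(c("group", "roi", "rho") %in% names(mrt_link)))
    if (abs(mrt_link$rho) >= 1) stop("mrt_link rho must satisfy |rho| < 1")
    if (!mrt_link$group %in% group_labels)
      stop("mrt_link group must be one of the cohort groups")
    stopifnot(mrt_link$roi >= 1L, mrt_link$roi <= n_rois)
    if (is.null(mrt_link$metric)) mrt_link$metric <- "betweenness"
    stopifnot(mrt_link$metric %in% c("betweenness", "degree"))
  }
  stopifnot(female_prop >= 0, female_prop <= 1,
            abs(ar_coef) < 1, n_frames >= 3L, mrt_sdlog > 0)
  structure(list(
    n_subjects_per_group = n_subjects_per_group, n_rois = n_rois,
    n_frames = as.integer(n_frames), sampling_interval = sampling_interval,
    modules = as.integer(modules), within_module_corr = within_module_corr,
    between_module_corr = between_module_corr, hub_roi = hub_roi,
    hub_boost = hub_boost, group_effects = group_effects,
    mrt_link = mrt_link, group_labels = group_labels,
    female_prop = female_prop, ar_coef = ar_coef,
    mrt_meanlog = mrt_meanlog, mrt_sdlog = mrt_sdlog,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Target correlation matrix implied by a cohort configuration
#'
#' Builds the block-structured correlation target: unit diagonal,
#' `within_module_corr` inside communities, `between_module_corr` across,
#' hub row/column raised by `hub_boost` (clipped below 1). If the result
#' is not positive semi-definite it is repaired by clipping negative
#' eigenvalues at zero and re-normalizing to unit diagonal; the repair is
#' recorded in the `"psd_repaired"` attribute and warned about. Targets
#' whose smallest eigenvalue is below -0.5 are rejected as
#' non-repairable.
#'
#' @param config a [cohort_config].
#' @param group optional group label whose `group_effects` multipliers are
#'   applied.
#' @return Correlation matrix with attribute `psd_repaired`.
#' @export
build_correlation_target <- function(config, group = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  wi <- config$within_module_corr
  bw <- config$between_module_corr
  if (!is.null(group) && !is.null(config$group_effects[[group]])) {
    eff <- config$group_effects[[group]]
    if (!is.na(eff["within"])) wi <- wi * eff[["within"]]
    if (!is.na(eff["between"])) bw <- bw * eff[["between"]]
    if (!(bw >= 0 && bw <= wi && wi < 1))
      stop("group_effects for '", group, "' violate 0 <= between <= within < 1")
  }
  n <- config$n_rois
  R <- matrix(bw, n, n)
  for (m in unique(config$modules)) {
    ix <- which(config$modules == m)
    R[ix, ix] <- wi
  }
  if (!is.null(config$hub_roi)) {
    h <- config$hub_roi
    R[h, -h] <- pmin(R[h, -h] + config$hub_boost, 1 - 1e-6)
    R[-h, h] <- R[h, -h]
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  repaired <- FALSE
  if (min(ev$values) < -0.5)
    stop("correlation target is not repairable (eigenvalue ",
         signif(min(ev$values), 3), " < -0.5)")
  if (min(ev$values) < -1e-10) {
    warning("correlation target repaired by eigenvalue clipping")
    vals <- pmax(ev$values, 0)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    R <- stats::cov2cor(R)
    R <- (R + t(R)) / 2
    diag(R) <- 1
    repaired <- TRUE
  }
  attr(R, "psd_repaired") <- repaired
  R
}

#' Sample a multivariate Gaussian ROI time-series
#'
#' Draws `n_frames` frames whose empirical correlation converges to the
#' target as the frame count grows. Temporal structure is optional AR(1)
#' smoothing of the latent noise with variance-preserving scaling, which
#' leaves the cross-sectional correlation target untouched.
#'
#' @param target PSD correlation matrix (e.g. from
#'   [build_correlation_target()]).
#' @param n_frames number of frames (>= 3).
#' @param seed optional RNG seed.
#' @param ar_coef AR(1) lag coefficient in (-1, 1); default 0.
#' @param sampling_interval seconds per frame.
#' @param roi_labels optional column labels; defaults to the target's
#'   dimnames or `ROI1..ROIn`.
#' @return A [roi_timeseries].
#' @export
sample_timeseries <- function(target, n_frames, seed = NULL, ar_coef = 0,
                              sampling_interval = 0.72, roi_labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target <- as.matrix(target)
  n <- nrow(target)
  if (n_frames < 3L) stop("at least 3 frames are required (correlation undefined below)")
  ev <- eigen(target, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("target must be positive semi-definite")
  fac <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n)
  z <- matrix(stats::rnorm(n_frames * n), n_frames, n)
  if (ar_coef != 0) {
    z <- apply(z, 2L, function(e)
      as.numeric(stats::filter(e * sqrt(1 - ar_coef^2), ar_coef,
                               method = "recursive")))
  }
  x <- z %*% t(fac)
  if (is.null(roi_labels))
    roi_labels <- colnames(target) %||% paste0("ROI", seq_len(n))
  roi_timeseries(x, roi_labels = roi_labels,
                 sampling_interval = sampling_interval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Task-score sampler with a left-skewed marginal
#'
#' Scores are generated as 27 minus a Poisson(11) right tail, redrawn until
#' they land in \[3, 27\]: a discrete, left-skewed distribution (median
#' near 16) emulating a correct-response count on a 27-item reasoning
#' task where most subjects answer most items correctly.
#'
#' @param n number of scores.
#' @param lower,upper optional restriction interval (used to draw scores
#'   consistent with an assigned IQ group).
#' @return Integer vector of scores.
#' @export
r_iq_scores <- function(n, lower = 3L, upper = 27L) {
  stopifnot(lower >= 3L, upper <= 27L, lower <= upper)
  out <- integer(0)
  while (length(out) < n) {
    draw <- 27L - stats::rpois(max(2L * n, 50L), lambda = 11)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

.group_score_interval <- function(group) {
  switch(group,
         low = c(4L, 10L),
         high = c(22L, 24L),
         mid = c(11L, 21L),
         stop("unknown group '", group, "'"))
}

#' Simulate subject metadata
#'
#' Generates one record per subject: gender (Bernoulli with the configured
#' female proportion), an IQ score drawn from the left-skewed score
#' distribution restricted to the subject's group interval, and a median
#' response time (MRT, ms) with a lognormal marginal. When the
#' configuration plants an MRT link `(group, roi, rho)`, the MRT of that
#' group is instead built linearly from the latent model
#' `MRT = mu + s * (rho * z + sqrt(1 - rho^2) * eps)` with `z` the
#' standardized metric value at the planted ROI and `mu`, `s` the mean and
#' SD implied by the lognormal marginal, so the population Pearson
#' correlation between the metric and MRT equals `rho` exactly (an
#' exponential link would inflate the correlation when the metric is
#' right-skewed, as tree betweenness is).
#'
#' @param config a [cohort_config].
#' @param per_subject_metric subjects-by-ROI matrix of metric values with
#'   subject ids as row names; required when `mrt_link` is set.
#' @return data.frame with columns `subject_id`, `gender`, `iq_score`,
#'   `mrt`, `group`.
#' @export
simulate_metadata <- function(config, per_subject_metric = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  link <- config$mrt_link
  groups <- rep(config$group_labels,
                times = config$n_subjects_per_group[config$group_labels])
  n <- length(groups)
  ids <- sprintf("S%04d", seq_len(n))
  gender <- ifelse(stats::runif(n) < config$female_prop, "female", "male")
  iq <- integer(n)
  for (g in unique(groups)) {
    iv <- .group_score_interval(g)
    sel <- groups == g
    iq[sel] <- r_iq_scores(sum(sel), iv[1L], iv[2L])
  }
  latent <- stats::rnorm(n)
  mrt <- exp(config$mrt_meanlog + config$mrt_sdlog * latent)
  if (!is.null(link)) {
    if (is.null(per_subject_metric))
      stop("per_subject_metric is required when mrt_link is configured")
    stopifnot(nrow(per_subject_metric) == n)
    sel <- which(groups == link$group)
    m <- per_subject_metric[sel, link$roi]
    if (stats::sd(m) == 0)
      stop("planted metric at ROI ", link$roi, " is constant; cannot plant correlation")
    z <- as.numeric(scale(m))
    mu <- exp(config$mrt_meanlog + config$mrt_sdlog^2 / 2)
    s <- mu * sqrt(exp(config$mrt_sdlog^2) - 1)
    lin <- link$rho * z + sqrt(1 - link$rho^2) * latent[sel]
    # linear in the metric => Pearson correlation is exactly rho; floor
    # guards the (vanishingly rare) nonpositive draw
    mrt[sel] <- pmax(mu + s * lin, 1)
  }
  data.frame(subject_id = ids, gender = gender, iq_score = iq,
             mrt = mrt, group = groups, stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' Seeds the RNG from the configuration and generates, per subject, an ROI
#' time-series from the group's correlation target, then the metadata
#' table. When an MRT link is planted, each subject's connectivity matrix
#' and maximum spanning tree are computed so the linked tree metric
#' (betweenness or degree) can drive the MRT construction.
#'
#' @param config a [cohort_config].
#' @return An object of class `cohort`: list with `timeseries` (named list
#'   of [roi_timeseries]), `metadata` (data.frame), `targets` (per-group
#'   correlation targets), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  targets <- lapply(stats::setNames(config$group_labels, config$group_labels),
                    function(g) build_correlation_target(config, group = g))
  groups <- rep(config$group_labels,
                times = config$n_subjects_per_group[config$group_labels])
  n <- length(groups)
  ids <- sprintf("S%04d", seq_len(n))
  labels <- paste0("ROI", seq_len(config$n_rois))
  ts <- vector("list", n)
  for (s in seq_len(n)) {
    ts[[s]] <- sample_timeseries(targets[[groups[s]]], config$n_frames,
                                 ar_coef = config$ar_coef,
                                 sampling_interval = config$sampling_interval,
                                 roi_labels = labels)
  }
  names(ts) <- ids
  metric <- NULL
  if (!is.null(config$mrt_link)) {
    metric <- matrix(NA_real_, n, config$n_rois, dimnames = list(ids, labels))
    for (s in seq_len(n)) {
      tree <- maximum_spanning_tree(build_connectivity(ts[[s]]))
      loc <- mst_local_metrics(tree)
      metric[s, ] <- loc[[config$mrt_link$metric]]
    }
  }
  metadata <- simulate_metadata(config, per_subject_metric = metric)
  structure(list(timeseries = ts, metadata = metadata, targets = targets,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d ROIs x %d frames\n",
              nrow(x$metadata),
              paste(sprintf("%s=%d", names(table(x$metadata$group)),
                            table(x$metadata$group)), collapse = ", "),
              x$config$n_rois, x$config$n_frames))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per-subject TSV time-series (`<id>.tsv`, ROI-name header) plus a
#' `metadata.csv` with columns subject_id, gender, iq_score, mrt, group.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$timeseries))
    write_roi_timeseries(cohort$timeseries[[id]], file.path(dir, paste0(id, ".tsv")))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Clustered modular weighted graph with strong shortcuts
#'
#' A synthetic small-world weighted network: ROIs are split into modules
#' whose within-module edges are all present at weight `within` (dense
#' strong triangles, i.e. high clustering); a small fraction `p_shortcut`
#' of between-module pairs carries a strong shortcut at the same weight
#' (long-range coupling, keeping path lengths short, the Watts-Strogatz
#' mechanism); and each remaining between-module pair is present
#' independently with probability `p_between` at the weak weight
#' `between` (the residual cross-module correlations that survive
#' negative-value discard). Resampled until connected.
#'
#' @param n nodes (default 27).
#' @param n_modules number of modules (default 4).
#' @param within,between strong / weak edge weights (defaults 0.6 / 0.1).
#' @param p_between inclusion probability for weak between-module edges.
#' @param p_shortcut probability a between-module pair is a strong
#'   shortcut instead (default 0.05, about one per node).
#' @param seed optional RNG seed.
#' @return A [connectivity_matrix].
#' @export
modular_weight_graph <- function(n = 27, n_modules = 4, within = 0.6,
                                 between = 0.1, p_between = 0.2,
                                 p_shortcut = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  modules <- sort(rep_len(seq_len(n_modules), n))
  repeat {
    w <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (modules[i] == modules[j]) w[i, j] <- within
        else if (stats::runif(1) < p_shortcut) w[i, j] <- within
        else if (stats::runif(1) < p_between) w[i, j] <- between
      }
    }
    w <- w + t(w)
    conn <- connectivity_matrix(w, roi_labels = paste0("ROI", seq_len(n)))
    if (igraph::is_connected(.conn_graph(conn))) return(conn)
  }
}
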
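#' End-to-end analysis pipeline
#'
#' Runs the full chain on a cohort: per-subject connectivity, small-world
#' panel against null ensembles, maximum spanning tree with local and
#' global descriptors, population hub profiles (per group and group x
#' gender), per-group metric-MRT correlations (degree and betweenness),
#' and the FDR-corrected group contrasts. Deterministic given the seed.
#'
#' @param cohort a `cohort` (from [simulate_cohort()] or assembled from
#'   read data: list with `timeseries` and `metadata`).
#' @param config alternatively, a [cohort_config] to simulate first.
#' @param n_null null-ensemble size per subject (default 100).
#' @param iterations_per_edge swap attempts per edge per null.
#' @param alpha FDR level for the contrasts.
#' @param seed seed for the small-world null ensembles.
#' @param small_world compute the small-world panel (set `FALSE` to skip
#'   the null ensembles when only tree metrics are needed).
#' @param out_dir optional output directory; when given, all tables are
#'   written as TSV plus a JSON run manifest.
#' @return List with `metric_table`, `local_metrics` (list of
#'   subjects-by-ROI matrices for degree/betweenness/eccentricity, raw and
#'   normalized), `trees`, `hub_profiles`, `mrt_correlations`,
#'   `comparisons`, and `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, config = NULL, n_null = 100,
                         iterations_per_edge = 10, alpha = 0.05, seed = NULL,
                         small_world = TRUE, out_dir = NULL) {
  if (is.null(cohort)) {
    if (is.null(config)) stop("either a cohort or a config is required")
    cohort <- simulate_cohort(config)
  }
  meta <- cohort$metadata
  ids <- meta$subject_id
  stopifnot(!anyDuplicated(ids), setequal(ids, names(cohort$timeseries)))
  if (!is.null(seed)) set.seed(seed)
  n_sub <- length(ids)
  roi_labels <- colnames(cohort$timeseries[[1L]])
  n_rois <- length(roi_labels)
  mk <- function() matrix(NA_real_, n_sub, n_rois, dimnames = list(ids, roi_labels))
  local_metrics <- list(degree = mk(), degree_norm = mk(),
                        betweenness = mk(), betweenness_norm = mk(),
                        eccentricity = mk(), eccentricity_norm = mk())
  global_cols <- c("c_w", "l_w", "gamma", "lambda", "sigma", "conn",
                   "d", "r", "l_f", "t_h", "kappa", "r_deg")
  gm <- matrix(NA_real_, n_sub, length(global_cols),
               dimnames = list(ids, global_cols))
  trees <- vector("list", n_sub)
  names(trees) <- ids
  for (s in seq_len(n_sub)) {
    id <- ids[s]
    conn <- tryCatch(build_connectivity(cohort$timeseries[[id]]),
                     error = function(e)
                       stop("stage connectivity failed for subject ", id, ": ",
                            conditionMessage(e)))
    if (small_world) {
      sw <- small_worldness(conn, n_null = n_null,
                            iterations_per_edge = iterations_per_edge)
      gm[s, c("c_w", "l_w", "gamma", "lambda", "sigma")] <-
        c(sw$c_w, sw$l_w, sw$gamma, sw$lambda, sw$sigma)
    } else {
      cl <- weighted_clustering(conn)
      gm[s, "c_w"] <- cl$mean
      gm[s, "l_w"] <- as.numeric(
        characteristic_path_length(shortest_path_lengths(conn)))
    }
    gm[s, "conn"] <- connectivity_cost(conn)
    tree <- maximum_spanning_tree(conn)
    trees[[s]] <- tree
    loc <- mst_local_metrics(tree)
    for (nm in names(local_metrics)) local_metrics[[nm]][s, ] <- loc[[nm]]
    glob <- mst_global_metrics(tree, loc)
    gm[s, c("d", "r", "l_f", "t_h", "kappa", "r_deg")] <-
      c(glob$diameter, glob$radius, glob$leaf_fraction,
        glob$tree_hierarchy, glob$kappa, glob$degree_correlation)
  }
  metric_table <- cbind(meta, as.data.frame(gm))
  populations <- .population_index(meta)
  hub_profiles <- list()
  for (pn in names(populations)) {
    sel <- populations[[pn]]
    hub_profiles[[paste0(pn, ".betweenness")]] <-
      hub_fractions(local_metrics$betweenness_norm, population = sel)
    hub_profiles[[paste0(pn, ".degree")]] <-
      hub_fractions(local_metrics$degree_norm, population = sel)
  }
  mrt_correlations <- list()
  for (g in unique(meta$group)) {
    sel <- which(meta$group == g)
    if (length(sel) < 4L) next
    mrt_correlations[[paste0(g, ".degree")]] <-
      mrt_correlation(local_metrics$degree_norm, meta$mrt, population = sel)
    mrt_correlations[[paste0(g, ".betweenness")]] <-
      mrt_correlation(local_metrics$betweenness_norm, meta$mrt, population = sel)
  }
  stat_metrics <- intersect(global_cols, colnames(gm)[colSums(is.finite(gm)) > 0])
  comparisons <- run_contrasts(metric_table, metrics = stat_metrics,
                               alpha = alpha, drop_empty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fcmst")),
    seed = seed,
    n_null = if (small_world) n_null else 0L,
    alpha = alpha,
    n_subjects = n_sub,
    n_rois = n_rois,
    n_connectivity = n_sub,
    n_trees = n_sub,
    group_counts = as.list(table(meta$group)),
    n_comparisons = nrow(comparisons)
  )
  result <- list(metric_table = metric_table, local_metrics = local_metrics,
                 trees = trees, hub_profiles = hub_profiles,
                 mrt_correlations = mrt_correlations,
                 comparisons = comparisons, manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

# populations for hub profiling: every group, plus group x gender
.population_index <- function(meta) {
  pops <- list()
  for (g in unique(meta$group)) {
    pops[[g]] <- which(meta$group == g)
    for (sx in unique(meta$gender)) {
      sel <- which(meta$group == g & meta$gender == sx)
      if (length(sel)) pops[[paste(g, sx, sep = ".")]] <- sel
    }
  }
  pops
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(result$metric_table, "metric_table.tsv")
  for (nm in names(result$local_metrics)) {
    m <- result$local_metrics[[nm]]
    wt(data.frame(subject_id = rownames(m), m, check.names = FALSE),
       paste0("local_", nm, ".tsv"))
  }
  hp <- do.call(rbind, lapply(names(result$hub_profiles), function(nm) {
    x <- result$hub_profiles[[nm]]
    data.frame(population = nm, roi = names(x), fraction = as.numeric(x))
  }))
  wt(hp, "hub_profiles.tsv")
  if (length(result$mrt_correlations)) {
    mc <- do.call(rbind, lapply(names(result$mrt_correlations), function(nm) {
      x <- result$mrt_correlations[[nm]]
      data.frame(population = nm, roi = names(x$r), r = as.numeric(x$r),
                 p = as.numeric(x$p),
                 is_best = names(x$r) == x$best_roi)
    }))
    wt(mc, "mrt_correlations.tsv")
  }
  wt(result$comparisons, "comparisons.tsv")
  for (id in names(result$trees))
    write_spanning_tree(result$trees[[id]],
                        file.path(out_dir, paste0("mst_", id, ".tsv")))
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
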
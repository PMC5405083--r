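test_that("correlation target follows the block construction rule", {
  # uniform single community
  cfg <- cohort_config(5, n_rois = 4, modules = rep(1, 4),
                       within_module_corr = 0.5, between_module_corr = 0.2,
                       hub_boost = 0)
  tg <- build_correlation_target(cfg)
  expect_equal(diag(tg), rep(1, 4))
  expect_equal(tg[upper.tri(tg)], rep(0.5, 6))
  # independence
  cfg0 <- cohort_config(5, n_rois = 4, modules = rep(1, 4),
                        within_module_corr = 0, between_module_corr = 0)
  expect_equal(build_correlation_target(cfg0), diag(4), ignore_attr = TRUE)
  # two communities of 3, checked cell by cell against the stated rule
  cfg2 <- cohort_config(5, n_rois = 6, modules = c(1, 1, 1, 2, 2, 2),
                        within_module_corr = 0.6, between_module_corr = 0.1)
  tg2 <- build_correlation_target(cfg2)
  mods <- c(1, 1, 1, 2, 2, 2)
  for (i in 1:6) {
    for (j in 1:6) {
      want <- if (i == j) 1 else if (mods[i] == mods[j]) 0.6 else 0.1
      expect_equal(tg2[i, j], want)
    }
  }
})

test_that("planted hub raises its row and column", {
  cfg <- cohort_config(5, n_rois = 6, modules = c(1, 1, 1, 2, 2, 2),
                       within_module_corr = 0.4, between_module_corr = 0.1,
                       hub_roi = 2, hub_boost = 0.2)
  tg <- build_correlation_target(cfg)
  expect_equal(tg[2, 1], 0.6)
  expect_equal(tg[2, 5], 0.3)
  expect_equal(tg[, 2], tg[2, ])
})

test_that("non-PSD targets are repaired by eigenvalue clipping or rejected", {
  # mildly indefinite: identity plus one boosted row
  cfg <- cohort_config(5, n_rois = 27, modules = rep(1, 27),
                       within_module_corr = 0, between_module_corr = 0,
                       hub_roi = 1, hub_boost = 0.2)
  expect_warning(tg <- build_correlation_target(cfg), "repaired")
  expect_true(attr(tg, "psd_repaired"))
  expect_true(min(eigen(tg, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
  expect_equal(diag(tg), rep(1, 27))
  # strongly indefinite: rejected
  cfg_bad <- cohort_config(5, n_rois = 27, modules = rep(1, 27),
                           within_module_corr = 0, between_module_corr = 0,
                           hub_roi = 1, hub_boost = 0.9)
  expect_error(build_correlation_target(cfg_bad), "not repairable")
})

test_that("sampled series converge to the target correlation", {
  set.seed(99)
  tg <- diag(4)
  ts <- sample_timeseries(tg, 1e5, seed = 1)
  r <- cor(ts)
  expect_lt(max(abs(r[upper.tri(r)])), 0.02)
  tg2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  ts2 <- sample_timeseries(tg2, 1e5, seed = 2)
  expect_gt(cor(ts2)[1, 2], 0.48)
  expect_lt(cor(ts2)[1, 2], 0.52)
})

test_that("sampling is bit-identical under a fixed seed and validates inputs", {
  tg <- matrix(c(1, 0.3, 0.3, 1), 2)
  a <- sample_timeseries(tg, 50, seed = 7)
  b <- sample_timeseries(tg, 50, seed = 7)
  expect_identical(a, b)
  expect_error(sample_timeseries(tg, 2, seed = 1), "3 frames")
})

test_that("AR(1) smoothing preserves the cross-sectional correlation target", {
  tg <- matrix(c(1, 0.5, 0.5, 1), 2)
  ts <- sample_timeseries(tg, 5e4, seed = 3, ar_coef = 0.4)
  expect_equal(cor(ts)[1, 2], 0.5, tolerance = 0.05)
  # and the induced lag-1 autocorrelation is near the coefficient
  x <- ts[, 1]
  expect_equal(cor(x[-1], x[-length(x)]), 0.4, tolerance = 0.05)
})

test_that("empirical correlation deviation is within 3/sqrt(n_frames) on 95% of entries", {
  cfg <- cohort_config(1, n_rois = 10, modules = rep(1:2, each = 5),
                       within_module_corr = 0.4, between_module_corr = 0.1,
                       hub_boost = 0)
  tg <- build_correlation_target(cfg)
  set.seed(5)
  for (nf in c(500, 2000)) {
    ts <- sample_timeseries(tg, nf)
    dev <- abs(cor(ts) - tg)[upper.tri(tg)]
    expect_gte(mean(dev <= 3 / sqrt(nf)), 0.95)
  }
})

test_that("task scores are discrete, bounded, and left-skewed", {
  set.seed(21)
  s <- r_iq_scores(1e4)
  expect_true(all(s >= 3 & s <= 27))
  expect_true(all(s == round(s)))
  expect_lt(sample_skewness(s), 0)
  # both tails populated
  expect_gt(sum(s <= 10), 0)
  expect_gt(sum(s >= 22), 0)
})

test_that("metadata respects groups, bounds, and gender proportions", {
  cfg <- cohort_config(c(low = 200, high = 150), n_rois = 6,
                       female_prop = 0.6)
  set.seed(31)
  md <- simulate_metadata(cfg)
  expect_equal(nrow(md), 350L)
  expect_true(all(md$iq_score >= 3 & md$iq_score <= 27))
  expect_true(all(md$iq_score[md$group == "low"] <= 10))
  expect_true(all(md$iq_score[md$group == "high"] >= 22))
  expect_true(all(md$mrt > 0))
  expect_equal(mean(md$gender == "female"), 0.6, tolerance = 0.12)
})

test_that("a null MRT link leaves metric correlations near zero", {
  cfg <- cohort_config(c(low = 500), n_rois = 8, group_labels = "low")
  set.seed(41)
  md <- simulate_metadata(cfg)
  metric <- matrix(rnorm(500 * 8), 500, 8,
                   dimnames = list(md$subject_id, paste0("ROI", 1:8)))
  rs <- cor(metric, md$mrt)
  expect_lt(max(abs(rs)), 0.15)
})

test_that("a planted rho = 0.5 link lands in its Fisher-z interval at n = 500", {
  cfg <- cohort_config(c(low = 500), n_rois = 8, group_labels = "low",
                       mrt_link = list(group = "low", roi = 3, rho = 0.5,
                                       metric = "betweenness"))
  set.seed(51)
  metric <- matrix(rnorm(500 * 8), 500, 8)
  rownames(metric) <- sprintf("S%04d", 1:500)
  md <- simulate_metadata(cfg, per_subject_metric = metric)
  r <- cor(metric[, 3], md$mrt)
  expect_gt(r, 0.42)
  expect_lt(r, 0.58)
})

test_that("mrt_link configuration is validated", {
  expect_error(cohort_config(5, mrt_link = list(group = "low", roi = 2, rho = 1)),
               "rho")
  cfg <- cohort_config(c(low = 10), n_rois = 4, group_labels = "low",
                       mrt_link = list(group = "low", roi = 2, rho = 0.4))
  expect_error(simulate_metadata(cfg), "per_subject_metric")
})

test_that("cohort simulation is bit-identical under a fixed seed", {
  cfg <- cohort_config(c(low = 3, high = 3), n_rois = 8, n_frames = 60,
                       seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$metadata, b$metadata)
})

test_that("a planted hub attains maximum tree degree in most subjects", {
  cfg <- cohort_config(c(low = 100), n_rois = 27, n_frames = 1200,
                       group_labels = "low", within_module_corr = 0.3,
                       between_module_corr = 0.1, hub_roi = 14,
                       hub_boost = 0.25, seed = 123)
  cohort <- simulate_cohort(cfg)
  hits <- 0L
  for (ts in cohort$timeseries) {
    tree <- maximum_spanning_tree(build_connectivity(ts))
    deg <- mst_local_metrics(tree)$degree
    if (14 %in% which(deg == max(deg))) hits <- hits + 1L
  }
  expect_gt(hits / 100, 0.5)
})

test_that("cohorts write per-subject TSVs plus a metadata CSV", {
  cfg <- cohort_config(c(low = 2), n_rois = 4, n_frames = 20,
                       group_labels = "low", seed = 5)
  cohort <- simulate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  files <- list.files(dir, pattern = "^S.*tsv$")
  expect_length(files, 2L)
  back <- read_roi_timeseries(file.path(dir, files[1]))
  expect_equal(ncol(back), 4L)
})
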